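#' Lagged regression of choices on recent outcomes
#'
#' Model-agnostic readout of the learning rate: regresses the per-trial
#' response on the outcomes of the previous five trials plus two
#' expected-reward predictors, separately per cue frame and task phase.
#' In the gaze frame the outcome is `y` (follow/not) and the lagged
#' predictors are the past gaze accuracies; in the card frame the
#' outcome is "blue taken" and the lagged predictors the past card
#' outcomes.  The least-squares slope of the fitted lag coefficients
#' over lag index summarizes how strongly recent trials dominate (a
#' steeper negative-going profile over increasing lag = higher effective
#' learning rate).
#'
#' Trials whose lag window crosses a phase boundary are excluded rather
#' than zero-padded.  The default family is binomial (logistic link);
#' a linear-probability fit is available for sensitivity checks.  On
#' perfect separation the fit falls back to a ridge-penalized logistic
#' regression (penalty 1e-4) and is flagged.
#'
#' @param responses a `hgfs_responses`.
#' @param experiment the matching `hgfs_experiment`.
#' @param schedule the matching `hgfs_schedule`.
#' @param frame `"card"` or `"gaze"`.
#' @param phase `"all"`, `"stable"` or `"volatile"` (phase of the chosen
#'   frame's stream).
#' @param lags number of outcome lags (default 5).
#' @param family `"binomial"` or `"gaussian"`.
#' @return object of class `hgfs_glm`: `coefficients` (named vector),
#'   `se`, `lag_coefficients`, `lag_slope`, `n_trials`, `ridge`
#'   (logical), `frame`, `phase`.
#' @export
choice_sequence_glm <- function(responses, experiment, schedule,
                                frame = c("card", "gaze"),
                                phase = c("all", "stable", "volatile"),
                                lags = 5,
                                family = c("binomial", "gaussian")) {
  frame <- match.arg(frame)
  phase <- match.arg(phase)
  family <- match.arg(family)
  n <- nrow(experiment)

  if (frame == "gaze") {
    y <- responses$y
    u <- experiment$u_gaze
    rew <- cbind(rew_gaze = experiment$r_gaze,
                 rew_notgaze = experiment$r_notgaze)
    ph <- schedule$phase_gaze
  } else {
    y <- as.integer(responses$chosen_card == "blue")
    u <- experiment$u_card
    rew <- cbind(rew_blue = experiment$reward_blue,
                 rew_green = experiment$reward_green)
    ph <- schedule$phase_card
  }

  lagmat <- sapply(seq_len(lags), function(l) c(rep(NA, l), u)[seq_len(n)])
  colnames(lagmat) <- paste0("lag", seq_len(lags))

  keep <- !responses$missing & seq_len(n) > lags
  if (phase != "all") {
    # the whole lag window t-lags .. t must sit inside the phase
    in_phase <- ph == phase
    window_ok <- vapply(seq_len(n), function(t)
      t > lags && all(in_phase[(t - lags):t]), logical(1))
    keep <- keep & window_ok
  }
  if (sum(keep) < lags + 1)
    stop("fewer than lags + 1 observed trials in the requested phase window")

  X <- cbind(lagmat, rew)[keep, , drop = FALSE]
  yk <- y[keep]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)] - 1L]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  dat <- data.frame(y = yk, X)
  ridge <- FALSE
  if (family == "gaussian") {
    fit <- stats::lm(y ~ ., data = dat)
    coefs <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
  } else {
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (separated || any(abs(stats::coef(fit)[-1]) > 15)) {
      ridge <- TRUE
      rfit <- ridge_logistic(cbind(1, X), yk, lambda = 1e-4)
      coefs <- stats::setNames(rfit$beta, c("(Intercept)", colnames(X)))
      se <- stats::setNames(rfit$se, names(coefs))
    } else {
      coefs <- stats::coef(fit)
      se <- summary(fit)$coefficients[, "Std. Error"]
    }
  }
  lag_names <- colnames(lagmat)
  lag_coefs <- coefs[lag_names]
  lag_slope <- unname(stats::coef(
    stats::lm(lag_coefs ~ seq_along(lag_coefs)))[2])

  structure(list(coefficients = coefs, se = se,
                 lag_coefficients = lag_coefs, lag_slope = lag_slope,
                 n_trials = sum(keep), ridge = ridge,
                 frame = frame, phase = phase, family = family),
            class = "hgfs_glm")
}

# Newton-iterated logistic regression with an L2 penalty on all
# coefficients except the intercept; used only as a separation fallback.
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100,
                           tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(lambda, p); pen[1, 1] <- 0
  beta <- numeric(p)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    grad <- drop(crossprod(X, y - mu)) - pen %*% beta
    Hess <- crossprod(X * w, X) + pen
    step <- solve(Hess, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  Hess <- crossprod(X * (mu * (1 - mu)), X) + pen
  list(beta = beta, se = sqrt(diag(solve(Hess))))
}

#' @export
print.hgfs_glm <- function(x, ...) {
  cat("Choice-sequence GLM (", x$frame, " frame, ", x$phase,
      " phase, n = ", x$n_trials, ")\n", sep = "")
  print(round(x$coefficients, 4))
  cat("lag slope:", round(x$lag_slope, 4),
      if (x$ridge) "(ridge fallback)" else "", "\n")
  invisible(x)
}

#' Paired contrast of lag slopes between phases
#'
#' Paired t-test on the per-subject difference of lag-coefficient slopes
#' (stable minus volatile); delegates to [stats::t.test()].
#'
#' @param slopes_stable,slopes_volatile numeric vectors, one entry per
#'   subject, paired by position.
#' @return the `htest` object from [stats::t.test()].
#' @export
slope_phase_contrast <- function(slopes_stable, slopes_volatile) {
  if (length(slopes_stable) != length(slopes_volatile))
    stop("slope vectors must be paired (equal length)")
  if (length(slopes_stable) < 2) stop("need at least 2 paired subjects")
  d <- slopes_stable - slopes_volatile
  if (all(d == 0)) {
    # identical slopes: no effect, by convention t = 0
    out <- list(statistic = c(t = 0), parameter = c(df = length(d) - 1),
                p.value = 1, estimate = c(`mean difference` = 0),
                method = "Paired t-test", alternative = "two.sided")
    class(out) <- "htest"
    return(out)
  }
  stats::t.test(slopes_stable, slopes_volatile, paired = TRUE)
}
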