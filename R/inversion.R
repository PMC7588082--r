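#' Log joint density of data and parameters
#'
#' The response-model log-likelihood at the native-space parameters plus
#' the sum of Gaussian log prior densities of the free parameters in
#' their estimation spaces.  Parameter sets that drive the perceptual
#' filter into an invalid state (filter rejection) are mapped to a large
#' negative penalty (-1e10) so that line searches remain finite.
#'
#' @param theta named numeric vector of free parameters in estimation
#'   space.
#' @param experiment a `hgfs_experiment`.
#' @param responses a `hgfs_responses`.
#' @param spec a `hgfs_model_spec`.
#' @param priors a `hgfs_priors` table.
#' @return scalar log joint (or -1e10 on rejection).
#' @export
log_joint <- function(theta, experiment, responses, spec, priors) {
  free <- priors[!priors$fixed, , drop = FALSE]
  if (!setequal(names(theta), free$name))
    stop("`theta` must carry exactly the free parameters")
  # fixed parameters enter at their stored point value (the prior mean,
  # estimation space) and contribute no prior density
  full <- stats::setNames(priors$mean, priors$name)
  full[free$name] <- theta[free$name]
  native <- as.list(transform_parameters(full, priors, "to_native"))
  # any parameter-driven failure (filter rejection, or domain errors
  # from underflowed transforms in extreme line-search steps) is
  # penalized rather than propagated, keeping the search finite
  ll <- tryCatch(
    likelihood_series(spec, native, experiment, responses)$loglik,
    error = function(e) NA_real_)
  if (is.na(ll) || !is.finite(ll)) return(-1e10)
  lp <- sum(stats::dnorm(theta[free$name], mean = free$mean,
                         sd = sqrt(free$variance), log = TRUE))
  ll + lp
}

# Central-difference Hessian of fn at x (step per dimension in
# estimation space).
numerical_hessian <- function(fn, x, step = 1e-4) {
  d <- length(x)
  H <- matrix(NA_real_, d, d)
  f0 <- fn(x)
  for (i in seq_len(d)) {
    for (j in i:d) {
      ei <- ej <- numeric(d); ei[i] <- step; ej[j] <- step
      if (i == j) {
        H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / step^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) -
           fn(x - ei + ej) + fn(x - ei - ej)) / (4 * step^2)
      }
    }
  }
  H
}

# MAP + Laplace evidence for an arbitrary log-posterior.  Quasi-Newton
# (BFGS) from `start` plus seeded perturbed restarts; returns the best
# mode, the Laplace log evidence and diagnostics.  Kept separate from
# fit_subject so the machinery can be exercised on closed-form cases.
map_laplace <- function(logpost, start, perturb_sd, n_restarts = 4,
                        seed = 1, reltol = 1e-8, maxit = 500,
                        hessian_step = 1e-4) {
  d <- length(start)
  starts <- list(start)
  if (n_restarts > 1) {
    withr::with_seed(as.integer(seed), {
      for (r in seq_len(n_restarts - 1))
        starts[[r + 1]] <- start + stats::rnorm(d, 0, perturb_sd)
    })
  }
  neg <- function(x) -logpost(stats::setNames(x, names(start)))
  best <- NULL
  n_failed <- 0L
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(unname(s), neg, method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer restarts failed")
  mode <- stats::setNames(best$par, names(start))
  lj <- -best$value
  H <- numerical_hessian(function(x) logpost(stats::setNames(x, names(start))),
                         best$par, step = hessian_step)
  H[!is.finite(H)] <- 0
  negH <- -(H + t(H)) / 2
  regularized <- FALSE
  ch <- tryCatch(chol(negH), error = function(e) NULL)
  if (is.null(ch)) {
    # fall back to a diagonal ridge until positive definite
    ridge <- 1e-6
    while (is.null(ch) && ridge < 1e6) {
      ch <- tryCatch(chol(negH + diag(ridge, d)), error = function(e) NULL)
      ridge <- ridge * 10
    }
    if (is.null(ch)) {
      # last resort (e.g. a mode hard against a rejection boundary,
      # where finite differences are dominated by the penalty): keep
      # only the diagonal curvature
      ch <- chol(diag(pmax(abs(diag(negH)), 1e-6), d))
    }
    regularized <- TRUE
  }
  logdet <- 2 * sum(log(diag(ch)))
  lme <- lj + (d / 2) * log(2 * pi) - 0.5 * logdet
  list(mode = mode, log_joint = lj, lme = lme, hessian = H,
       diagnostics = list(converged = best$convergence == 0,
                          iterations = best$counts[["function"]],
                          restarts = length(starts),
                          restarts_failed = n_failed,
                          hessian_regularized = regularized))
}

#' Fit one subject by MAP estimation with Laplace model evidence
#'
#' Maximizes the log joint of one subject's data under a model with a
#' quasi-Newton (BFGS) search in estimation space, started from the
#' prior mean plus `n_restarts - 1` seeded Gaussian perturbations
#' (SD = prior SD / 4), keeping the best mode.  The log model evidence
#' is the Laplace approximation
#' `LME = log_joint(mode) + (d/2) log 2*pi - 0.5 log det(-H)`
#' with `H` the central-difference Hessian at the mode and `d` the
#' number of free parameters.
#'
#' @param experiment a `hgfs_experiment`.
#' @param responses a `hgfs_responses` with at least one observed trial.
#' @param spec a `hgfs_model_spec`.
#' @param priors a `hgfs_priors` table (default [default_priors()]).
#' @param n_restarts optimizer restarts (default 4).
#' @param seed integer seed for the restart perturbations.
#' @param reltol convergence tolerance on the objective.
#' @return object of class `hgfs_fit`: MAP estimates in estimation and
#'   native space, `lme`, `log_joint`, Hessian, optimizer diagnostics
#'   and the belief/decision trajectories at the mode.
#' @export
fit_subject <- function(experiment, responses, spec,
                        priors = default_priors(spec), n_restarts = 4,
                        seed = 1, reltol = 1e-8) {
  if (all(responses$missing)) stop("no observed trials to fit")
  free <- priors[!priors$fixed, , drop = FALSE]
  start <- stats::setNames(free$mean, free$name)
  lp <- function(theta) log_joint(theta, experiment, responses, spec, priors)
  res <- map_laplace(lp, start, perturb_sd = sqrt(free$variance) / 4,
                     n_restarts = n_restarts, seed = seed, reltol = reltol)
  full <- stats::setNames(priors$mean, priors$name)
  full[names(res$mode)] <- res$mode
  native <- as.list(transform_parameters(full, priors, "to_native"))
  traj <- NULL; decision <- NULL
  if (spec$perceptual != "none") {
    traj <- run_perceptual(spec, native, experiment)
    decision <- decision_trajectory(spec, traj, experiment, native)
  }
  structure(list(spec = spec, priors = priors,
                 estimates = res$mode, estimates_native = native,
                 lme = res$lme, log_joint = res$log_joint,
                 hessian = res$hessian, diagnostics = res$diagnostics,
                 trajectories = traj, decision = decision),
            class = "hgfs_fit")
}

#' @export
print.hgfs_fit <- function(x, ...) {
  cat("Model", x$spec$label, "fit: LME =", round(x$lme, 3), "\n")
  cat("MAP estimates (estimation space):\n")
  print(round(x$estimates, 4))
  invisible(x)
}

#' Fit several models to several subjects
#'
#' Convenience wrapper producing the subjects-by-models log-model-
#' evidence matrix consumed by [rfx_bms()].
#'
#' @param subjects list of lists with elements `experiment` and
#'   `responses` (e.g. the output of [generate_cohort()]).
#' @param specs list of `hgfs_model_spec` (default [model_space()]).
#' @param n_restarts,seed passed to [fit_subject()]; each subject/model
#'   pair receives a distinct derived seed.
#' @return list with `lme` (matrix, rownames subject indices, colnames
#'   model labels) and `fits` (list of lists of `hgfs_fit`).
#' @export
fit_cohort <- function(subjects, specs = model_space(), n_restarts = 2,
                       seed = 1) {
  labels <- vapply(specs, `[[`, "", "label")
  lme <- matrix(NA_real_, length(subjects), length(specs),
                dimnames = list(seq_along(subjects), labels))
  fits <- vector("list", length(subjects))
  seeds <- derive_seeds(seed, length(subjects) * length(specs))
  k <- 0L
  for (i in seq_along(subjects)) {
    fits[[i]] <- vector("list", length(specs))
    for (j in seq_along(specs)) {
      k <- k + 1L
      f <- fit_subject(subjects[[i]]$experiment, subjects[[i]]$responses,
                       specs[[j]], n_restarts = n_restarts,
                       seed = seeds[k])
      lme[i, j] <- f$lme
      fits[[i]][[j]] <- f
    }
    names(fits[[i]]) <- labels
  }
  list(lme = lme, fits = fits)
}

# deterministic stream of sub-seeds below 2^31
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max - 1L, n))
}
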