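#' Logistic sigmoid
#'
#' The mapping between the second-level tendency and the first-level
#' outcome probability, `s(x) = 1 / (1 + exp(-x))`.  Saturates without
#' overflow at extreme arguments.
#'
#' @param x numeric vector.
#' @return numeric vector in (0, 1).
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

# classed condition so the fitter can penalize a parameter set that drives
# the filter into an invalid state (e.g. negative posterior precision)
hgf_reject <- function(trial, what) {
  stop(structure(class = c("hgfs_rejection", "error", "condition"),
                 list(message = sprintf("filter rejection at trial %d: %s",
                                        trial, what),
                      call = NULL, trial = trial)))
}

#' Three-level binary hierarchical Gaussian filter (one stream)
#'
#' Runs the standard three-level binary HGF over one binary input series.
#' Level 1 is the observed outcome, level 2 the latent tendency (logit of
#' the outcome probability) and level 3 the log-volatility of that
#' tendency.  Levels 2 and 3 evolve as AR(1) processes; with the default
#' `phi = 0` this is the Gaussian random-walk limit.  On each trial the
#' filter forms predictions from the previous posteriors, observes the
#' input, and updates means and precisions with precision-weighted
#' prediction errors:
#'
#' \describe{
#'   \item{prediction}{`muhat2 = mu2 + phi2*(m2 - mu2)`; `muhat1 =
#'     s(muhat2)`; `pihat2 = 1/(sigma2 + exp(kappa*mu3 + omega2))`;
#'     `pihat3 = 1/(sigma3 + exp(omega3))`.}
#'   \item{update}{`delta1 = u - muhat1`; `pi2 = pihat2 +
#'     muhat1*(1 - muhat1)`; `mu2 = muhat2 + delta1/pi2`; the volatility
#'     prediction error `delta2 = (sigma2 + (mu2 - muhat2)^2)*pihat2 - 1`
#'     drives the third level with weight `w2 = exp(kappa*mu3 +
#'     omega2)*pihat2`.}
#' }
#'
#' Derived precision-weight series are attached: `psi2 = 1/pi2`,
#' `qpsi2 = psi2 * s(mu2) * (1 - s(mu2))` (an uncertainty measure for the
#' first-level belief, corrected for the sigmoid mapping) and
#' `psi3 = pihat2/pi3`.
#'
#' @param u binary input vector (0/1).
#' @param omega2 tonic log-volatility at level 2 (the stream's
#'   contingency learning rate parameter).
#' @param omega3 tonic log-volatility at level 3 (volatility learning
#'   rate parameter).
#' @param kappa coupling between levels 2 and 3 (fixed at 1 by default).
#' @param mu2_0,sigma2_0,mu3_0,sigma3_0 initial posterior means and
#'   variances.
#' @param phi2,phi3 AR(1) coefficients (0 = random walk).
#' @param m2,m3 AR(1) attractor points (used only when `phi > 0`).
#' @return data.frame of class `hgfs_trajectory`, one row per trial, with
#'   columns `muhat1, pihat1, delta1, muhat2, pihat2, mu2, pi2, sigma2,
#'   delta2, muhat3, pihat3, mu3, pi3, sigma3, psi2, qpsi2, psi3`.
#' @export
hgf_filter <- function(u, omega2 = -3, omega3 = -6, kappa = 1,
                       mu2_0 = 0, sigma2_0 = 1, mu3_0 = 1, sigma3_0 = 1,
                       phi2 = 0, m2 = mu2_0, phi3 = 0, m3 = mu3_0) {
  if (!all(u %in% c(0, 1))) stop("inputs `u` must be binary (0/1)")
  if (sigma2_0 <= 0 || sigma3_0 <= 0) stop("initial variances must be > 0")
  if (kappa <= 0) stop("`kappa` must be > 0")
  n <- length(u)
  cols <- c("muhat1", "pihat1", "delta1", "muhat2", "pihat2", "mu2", "pi2",
            "sigma2", "delta2", "muhat3", "pihat3", "mu3", "pi3", "sigma3",
            "psi2", "qpsi2", "psi3")
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))

  mu2 <- mu2_0; sigma2 <- sigma2_0
  mu3 <- mu3_0; sigma3 <- sigma3_0
  for (k in seq_len(n)) {
    # prediction step
    muhat2 <- mu2 + phi2 * (m2 - mu2)
    muhat3 <- mu3 + phi3 * (m3 - mu3)
    pihat2 <- 1 / (sigma2 + exp(kappa * mu3 + omega2))
    pihat3 <- 1 / (sigma3 + exp(omega3))
    muhat1 <- sigmoid(muhat2)
    muhat1 <- min(max(muhat1, 1e-8), 1 - 1e-8)
    pihat1 <- 1 / (muhat1 * (1 - muhat1))
    if (!is.finite(pihat2) || pihat2 <= 0) hgf_reject(k, "pihat2 <= 0")

    # update step, level 2
    delta1 <- u[k] - muhat1
    pi2 <- pihat2 + muhat1 * (1 - muhat1)
    mu2_new <- muhat2 + delta1 / pi2

    # volatility prediction error and level 3
    delta2 <- (1 / pi2 + (mu2_new - muhat2)^2) * pihat2 - 1
    w2 <- exp(kappa * mu3 + omega2) * pihat2
    pi3 <- pihat3 + 0.5 * kappa^2 * w2 * (w2 + (2 * w2 - 1) * delta2)
    if (!is.finite(pi3) || pi3 <= 1e-12) hgf_reject(k, "pi3 <= 0")
    mu3_new <- muhat3 + 0.5 * (1 / pi3) * kappa * w2 * delta2
    if (!is.finite(mu3_new) || !is.finite(mu2_new))
      hgf_reject(k, "non-finite posterior mean")

    mu2 <- mu2_new; sigma2 <- 1 / pi2
    mu3 <- mu3_new; sigma3 <- 1 / pi3
    out[k, ] <- c(muhat1, pihat1, delta1, muhat2, pihat2, mu2, pi2, sigma2,
                  delta2, muhat3, pihat3, mu3, pi3, sigma3,
                  1 / pi2, (1 / pi2) * sigmoid(mu2) * (1 - sigmoid(mu2)),
                  pihat2 / pi3)
  }
  out <- as.data.frame(out)
  attr(out, "params") <- list(omega2 = omega2, omega3 = omega3, kappa = kappa,
                              mu2_0 = mu2_0, sigma2_0 = sigma2_0,
                              mu3_0 = mu3_0, sigma3_0 = sigma3_0,
                              phi2 = phi2, m2 = m2, phi3 = phi3, m3 = m3)
  class(out) <- c("hgfs_trajectory", "data.frame")
  out
}

#' Precision-weight series derived from a trajectory
#'
#' Recomputes the dynamic learning-rate quantities from the stored
#' posterior means and precisions: `psi2 = 1/pi2`, `qpsi2 = psi2 * s(mu2)
#' * (1 - s(mu2))` and `psi3 = pihat2/pi3`.  These are the quantities
#' averaged by phase in the precision-weight summaries.
#'
#' @param trajectory a `hgfs_trajectory`.
#' @return data.frame with columns `psi2`, `qpsi2`, `psi3`.
#' @export
derived_precision_weights <- function(trajectory) {
  need <- c("pi2", "mu2", "pihat2", "pi3")
  if (!all(need %in% names(trajectory)))
    stop("trajectory lacks required columns")
  if (any(trajectory$pi2 <= 0) || any(trajectory$pi3 <= 0))
    stop("non-positive precision in trajectory")
  psi2 <- 1 / trajectory$pi2
  s <- sigmoid(trajectory$mu2)
  data.frame(psi2 = psi2, qpsi2 = psi2 * s * (1 - s),
             psi3 = trajectory$pihat2 / trajectory$pi3)
}

#' Rescorla-Wagner filter (one stream)
#'
#' Delta-rule learner with a fixed learning rate:
#' `v(k) = v(k-1) + alpha * (u(k) - v(k-1))`, starting from `v0 = 0.5`.
#' The column `vhat` holds the prediction used on trial k (the value
#' before the update).
#'
#' @param u binary input vector.
#' @param alpha learning rate in \[0, 1\].
#' @param v0 initial value (default 0.5).
#' @return data.frame with columns `vhat`, `delta`, `v`.
#' @export
rw_filter <- function(u, alpha, v0 = 0.5) {
  if (!all(u %in% c(0, 1))) stop("inputs `u` must be binary (0/1)")
  if (length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("`alpha` must lie in [0, 1]")
  n <- length(u)
  vhat <- delta <- v <- numeric(n)
  vprev <- v0
  for (k in seq_len(n)) {
    vhat[k] <- vprev
    delta[k] <- u[k] - vprev
    vprev <- vprev + alpha * delta[k]
    v[k] <- vprev
  }
  data.frame(vhat = vhat, delta = delta, v = v)
}

#' Sutton K1 filter (one stream)
#'
#' Delta-rule learner whose gain adapts to the recent history of
#' prediction errors (Sutton's K1 rule for a scalar input).  A log-gain
#' `b` is incremented by the meta-learning rate times the product of the
#' current prediction error and an exponentially decaying trace `h` of
#' recent error-driven updates, so that runs of same-signed errors
#' (systematic misprediction) raise the learning rate while alternating
#' errors lower it:
#'
#' \preformatted{
#'   delta(k) = u(k) - v(k-1)
#'   b(k)     = b(k-1) + mu * delta(k) * h(k-1)
#'   alpha(k) = min(exp(b(k)), 1)
#'   v(k)     = v(k-1) + alpha(k) * delta(k)
#'   h(k)     = h(k-1) * max(0, 1 - alpha(k)) + alpha(k) * delta(k)
#' }
#'
#' With `mu = 0` the gain stays at `exp(b0)` and the rule reduces to
#' Rescorla-Wagner.
#'
#' @param u binary input vector.
#' @param mu meta-learning rate (> 0, or 0 for the fixed-gain limit).
#' @param b0 initial log-gain (default `log(0.1)`).
#' @param v0 initial value (default 0.5).
#' @return data.frame with columns `vhat`, `delta`, `v`, `alpha`,
#'   `loggain`.
#' @export
sutton_k1_filter <- function(u, mu, b0 = log(0.1), v0 = 0.5) {
  if (!all(u %in% c(0, 1))) stop("inputs `u` must be binary (0/1)")
  if (length(mu) != 1L || mu < 0) stop("`mu` must be >= 0")
  n <- length(u)
  vhat <- delta <- v <- alpha <- loggain <- numeric(n)
  vprev <- v0; h <- 0; b <- b0
  for (k in seq_len(n)) {
    vhat[k] <- vprev
    delta[k] <- u[k] - vprev
    b <- b + mu * delta[k] * h
    a <- min(exp(b), 1)
    if (!is.finite(a) || a <= 0) hgf_reject(k, "non-finite K1 gain")
    vprev <- vprev + a * delta[k]
    h <- h * max(0, 1 - a) + a * delta[k]
    v[k] <- vprev; alpha[k] <- a; loggain[k] <- b
  }
  data.frame(vhat = vhat, delta = delta, v = v, alpha = alpha,
             loggain = loggain)
}
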