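#' Default Gaussian priors for a model's free parameters
#'
#' Priors are specified in the estimation space of each parameter
#' (native for the tonic log-volatilities, log for the positive-domain
#' `zeta` and `beta`, logit for unit-interval parameters).  Defaults are
#' weakly informative: `omega2 ~ N(-3, 16)` and `omega3 ~ N(-6, 16)` in
#' native space, `log zeta`, `log beta` and `logit eta ~ N(0, 4)`,
#' Rescorla-Wagner `logit alpha`, WSLS `logit epsilon` and random-model
#' `logit bias ~ N(0, 1)`, and K1 `log mu ~ N(-2, 4)`.  All values are
#' overridable by editing the returned table.
#'
#' @param spec a `hgfs_model_spec`.
#' @return data.frame of class `hgfs_priors` with columns `name`,
#'   `space`, `mean`, `variance`, `fixed` (logical).
#' @export
default_priors <- function(spec) {
  tab <- model_parameters(spec)
  mean <- numeric(nrow(tab)); variance <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    if (startsWith(nm, "omega2")) { mean[i] <- -3; variance[i] <- 16 }
    else if (startsWith(nm, "omega3")) { mean[i] <- -6; variance[i] <- 16 }
    else if (nm %in% c("zeta", "beta")) { mean[i] <- 0; variance[i] <- 4 }
    else if (nm == "eta") { mean[i] <- 0; variance[i] <- 4 }
    else if (startsWith(nm, "mu_")) { mean[i] <- -2; variance[i] <- 4 }
    else { mean[i] <- 0; variance[i] <- 1 }   # alpha, epsilon, bias
  }
  out <- data.frame(name = tab$name, space = tab$space, mean = mean,
                    variance = variance, fixed = FALSE)
  class(out) <- c("hgfs_priors", "data.frame")
  out
}

#' Transform parameters between native and estimation space
#'
#' `log`-space parameters map via `exp`/`log`, `logit`-space via the
#' logistic sigmoid and its inverse, `native` is the identity.  The
#' round trip is the identity to better than 1e-12.
#'
#' @param values named numeric vector or list.
#' @param priors a `hgfs_priors` table (only `name` and `space` are
#'   used), or a data.frame with those columns.
#' @param direction `"to_native"` (estimation space in, native out) or
#'   `"to_estimation"`.
#' @return named numeric vector in the target space.
#' @export
transform_parameters <- function(values, priors,
                                 direction = c("to_native",
                                               "to_estimation")) {
  direction <- match.arg(direction)
  values <- unlist(values)
  out <- values
  for (i in seq_along(values)) {
    nm <- names(values)[i]
    space <- priors$space[match(nm, priors$name)]
    if (is.na(space)) stop("unknown parameter: ", nm)
    x <- values[[i]]
    out[[i]] <- if (space == "native") x
      else if (space == "log") { if (direction == "to_native") exp(x) else {
        if (x <= 0) stop("log-space transform needs a positive value: ", nm)
        log(x) } }
      else { # logit
        # clamp away from the boundary: the sigmoid saturates to exactly
        # 0/1 in floating point for |x| > ~37
        if (direction == "to_native")
          min(max(sigmoid(x), 1e-12), 1 - 1e-12) else {
          if (x <= 0 || x >= 1)
            stop("logit transform needs a value in (0,1): ", nm)
          log(x / (1 - x)) } }
  }
  out
}
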