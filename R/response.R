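#' Model specification
#'
#' Pairs a perceptual family with a response variant.  The hierarchical
#' filter ("hgf") combines with response variants 1-4, which differ only
#' in how the inverse decision temperature is formed from the predicted
#' log-volatilities; the non-hierarchical learners ("rw", "k1") lack
#' third-level trajectories and therefore combine with variant 4 only.
#' The two non-learning baselines ("wsls", "random") need no perceptual
#' family.
#'
#' @param perceptual one of `"hgf"`, `"rw"`, `"k1"`, `"none"`.
#' @param response one of `1:4`, `"wsls"`, `"random"`.
#' @return object of class `hgfs_model_spec`.
#' @export
model_spec <- function(perceptual = c("hgf", "rw", "k1", "none"),
                       response = 1) {
  perceptual <- match.arg(perceptual)
  response <- as.character(response)
  if (!response %in% c("1", "2", "3", "4", "wsls", "random"))
    stop("`response` must be 1-4, \"wsls\" or \"random\"")
  if (response %in% c("1", "2", "3") && perceptual != "hgf")
    stop("response variants 1-3 require the hgf perceptual family")
  if (response %in% c("wsls", "random") && perceptual != "none")
    stop("wsls/random baselines take perceptual = \"none\"")
  if (perceptual != "none" && response %in% c("wsls", "random"))
    stop("baseline response models take no perceptual family")
  if (perceptual == "none" && response %in% c("1", "2", "3", "4"))
    stop("belief-based response variants require a perceptual family")
  label <- if (perceptual == "none") response
           else paste0(perceptual, response)
  structure(list(perceptual = perceptual, response = response,
                 label = label),
            class = "hgfs_model_spec")
}

#' The canonical eight-model comparison space
#'
#' HGF with response variants 1-4, the Sutton K1 and Rescorla-Wagner
#' learners with variant 4, and the win-stay-lose-shift and
#' random-responding baselines, in that order.
#'
#' @return named list of `hgfs_model_spec` objects.
#' @export
model_space <- function() {
  specs <- list(model_spec("hgf", 1), model_spec("hgf", 2),
                model_spec("hgf", 3), model_spec("hgf", 4),
                model_spec("k1", 4), model_spec("rw", 4),
                model_spec("none", "wsls"), model_spec("none", "random"))
  names(specs) <- vapply(specs, `[[`, "", "label")
  specs
}

#' Free parameters of a model, with estimation spaces
#'
#' @param spec a `hgfs_model_spec`.
#' @return data.frame with columns `name` (native-space parameter name)
#'   and `space` (`"native"`, `"log"` or `"logit"`).
#' @export
model_parameters <- function(spec) {
  stopifnot(inherits(spec, "hgfs_model_spec"))
  resp <- switch(spec$response,
    wsls = data.frame(name = "epsilon", space = "logit"),
    random = data.frame(name = "bias", space = "logit"),
    data.frame(name = c("zeta", "beta", "eta"),
               space = c("log", "log", "logit")))
  perc <- switch(spec$perceptual,
    hgf = data.frame(name = c("omega2_card", "omega2_gaze",
                              "omega3_card", "omega3_gaze"),
                     space = "native"),
    rw = data.frame(name = c("alpha_card", "alpha_gaze"), space = "logit"),
    k1 = data.frame(name = c("mu_card", "mu_gaze"), space = "log"),
    none = NULL)
  rbind(perc, resp)
}

#' Card prediction in the gaze frame
#'
#' Converts the belief that the blue card wins into the belief that the
#' card the gaze points at wins.
#'
#' @param muhat1_blue probability that blue wins.
#' @param gaze_target `"blue"` or `"green"` (vectorized).
#' @return probability that the gazed-at card wins.
#' @export
gaze_frame_card_prediction <- function(muhat1_blue, gaze_target) {
  if (!all(gaze_target %in% c("blue", "green")))
    stop("`gaze_target` must be \"blue\" or \"green\"")
  ifelse(gaze_target == "blue", muhat1_blue, 1 - muhat1_blue)
}

#' Combined belief from the two streams
#'
#' Merges the social prediction (gaze correct) and the gaze-frame
#' non-social prediction (gazed-at card wins) into a single belief that
#' following the gaze pays off.  Each prediction is weighted by its
#' Bernoulli precision `pihat = 1/(m(1-m))`; the social precision is
#' scaled by the weighting factor `zeta`, so `zeta > 1` means social
#' information is trusted beyond its nominal precision:
#' `w_gaze = zeta*pihat_gaze / (zeta*pihat_gaze + pihat_card)`,
#' `b = w_gaze*m_gaze + w_card*m_card`.
#'
#' @param muhat1_gaze predicted probability that the gaze is correct.
#' @param muhat1_card gaze-frame predicted probability that the gazed-at
#'   card wins.
#' @param zeta social weighting factor (> 0).
#' @return list with vectors `b`, `w_gaze`, `w_card`.
#' @export
combined_belief <- function(muhat1_gaze, muhat1_card, zeta) {
  if (zeta <= 0) stop("`zeta` must be > 0")
  mg <- pmin(pmax(muhat1_gaze, 1e-8), 1 - 1e-8)
  mc <- pmin(pmax(muhat1_card, 1e-8), 1 - 1e-8)
  pihat_gaze <- 1 / (mg * (1 - mg))
  pihat_card <- 1 / (mc * (1 - mc))
  w_gaze <- zeta * pihat_gaze / (zeta * pihat_gaze + pihat_card)
  w_card <- 1 - w_gaze
  list(b = w_gaze * mg + w_card * mc, w_gaze = w_gaze, w_card = w_card)
}

#' Inverse decision temperature
#'
#' Variant 1 modulates the noise scale `beta` by the predicted
#' log-volatility of both streams, variant 2 by the social stream only,
#' variant 3 by the non-social stream only; variant 4 is constant.
#'
#' @param variant response variant (1-4).
#' @param muhat3_card,muhat3_gaze predicted third-level means (ignored
#'   where the variant does not use them).
#' @param beta decision-noise scale (> 0).
#' @return vector of per-trial inverse temperatures.
#' @export
decision_temperature <- function(variant, muhat3_card = NULL,
                                 muhat3_gaze = NULL, beta) {
  if (beta <= 0) stop("`beta` must be > 0")
  variant <- as.character(variant)
  switch(variant,
    "1" = beta * exp(-muhat3_card - muhat3_gaze),
    "2" = beta * exp(-muhat3_gaze),
    "3" = beta * exp(-muhat3_card),
    "4" = beta,
    stop("unknown response variant: ", variant))
}

#' Probability of following the gaze
#'
#' Reward-weighted softmax of the combined belief.  The belief is
#' weighted by the reward on the gazed-at card (`r_gaze`) against the
#' reward on the other card (`r_notgaze`); the mixing parameter `eta`
#' interpolates between linear (`eta = 1`) and logarithmic (`eta = 0`)
#' reward weighting, absorbing subject-specific non-linear distortions of
#' reward value.
#'
#' @param b combined belief in (0, 1).
#' @param r_gaze,r_notgaze reward values (>= 1).
#' @param gamma inverse decision temperature (> 0), scalar or per trial.
#' @param eta linear/log reward mixing weight in \[0, 1\].
#' @return probability of `y = 1` (follow).
#' @export
prob_follow_gaze <- function(b, r_gaze, r_notgaze, gamma, eta) {
  if (any(r_gaze < 1) || any(r_notgaze < 1))
    stop("rewards must be >= 1 (logarithmic weighting)")
  if (eta < 0 || eta > 1) stop("`eta` must lie in [0, 1]")
  eta * sigmoid(gamma * (r_gaze * b - r_notgaze * (1 - b))) +
    (1 - eta) * sigmoid(gamma * (log(r_gaze) * b - log(r_notgaze) * (1 - b)))
}

# Run the perceptual filters of a spec on an experiment's inputs.
# Returns NULL for baseline models.
run_perceptual <- function(spec, params, experiment) {
  switch(spec$perceptual,
    hgf = list(
      card = hgf_filter(experiment$u_card, omega2 = params$omega2_card,
                        omega3 = params$omega3_card),
      gaze = hgf_filter(experiment$u_gaze, omega2 = params$omega2_gaze,
                        omega3 = params$omega3_gaze)),
    rw = list(
      card = rw_filter(experiment$u_card, alpha = params$alpha_card),
      gaze = rw_filter(experiment$u_gaze, alpha = params$alpha_gaze)),
    k1 = list(
      card = sutton_k1_filter(experiment$u_card, mu = params$mu_card),
      gaze = sutton_k1_filter(experiment$u_gaze, mu = params$mu_gaze)),
    none = NULL)
}

#' Per-trial decision quantities for a belief-based response model
#'
#' Combines a spec's perceptual trajectories into the gaze-frame decision
#' series: gaze-frame predictions, precision weights, combined belief,
#' inverse temperature and follow probability.
#'
#' @param spec a `hgfs_model_spec` with a perceptual family.
#' @param trajectories list with elements `card` and `gaze` from the
#'   perceptual filters.
#' @param experiment the `hgfs_experiment`.
#' @param params named list of native-space parameters (`zeta`, `beta`,
#'   `eta` plus perceptual parameters).
#' @return data.frame of class `hgfs_decision` with columns
#'   `muhat1_gaze`, `muhat1_card`, `w_gaze`, `w_card`, `b`, `gamma`,
#'   `prob_gaze`.
#' @export
decision_trajectory <- function(spec, trajectories, experiment, params) {
  stopifnot(inherits(spec, "hgfs_model_spec"))
  if (spec$perceptual == "none")
    stop("baseline models have no decision trajectory")
  if (spec$perceptual == "hgf") {
    muhat1_blue <- trajectories$card$muhat1
    muhat1_gaze <- trajectories$gaze$muhat1
    muhat3_card <- trajectories$card$muhat3
    muhat3_gaze <- trajectories$gaze$muhat3
  } else {
    muhat1_blue <- trajectories$card$vhat
    muhat1_gaze <- trajectories$gaze$vhat
    muhat3_card <- muhat3_gaze <- NULL
  }
  muhat1_card <- gaze_frame_card_prediction(muhat1_blue,
                                            experiment$gaze_target)
  cb <- combined_belief(muhat1_gaze, muhat1_card, params$zeta)
  gamma <- decision_temperature(spec$response, muhat3_card, muhat3_gaze,
                                params$beta)
  if (length(gamma) == 1L) gamma <- rep(gamma, nrow(experiment))
  prob <- prob_follow_gaze(cb$b, experiment$r_gaze, experiment$r_notgaze,
                           gamma, params$eta)
  out <- data.frame(muhat1_gaze = muhat1_gaze, muhat1_card = muhat1_card,
                    w_gaze = cb$w_gaze, w_card = cb$w_card, b = cb$b,
                    gamma = gamma, prob_gaze = prob)
  class(out) <- c("hgfs_decision", "data.frame")
  out
}

# WSLS follow probability series given observed (or simulated-so-far)
# responses.  "Stay" is defined on the chosen card; the stay probability
# is 1 - epsilon after a win and epsilon after a loss, mapped into the
# gaze frame via the current gaze target.  Trial 1 (and trials following
# a missed response) get 0.5.
wsls_prob_one <- function(t, prev_chosen, prev_rewarded, gaze_target,
                          epsilon) {
  if (t == 1L || is.na(prev_chosen) || is.na(prev_rewarded)) return(0.5)
  p_stay <- if (prev_rewarded == 1L) 1 - epsilon else epsilon
  if (gaze_target == prev_chosen) p_stay else 1 - p_stay
}

#' Per-trial choice probabilities and log-likelihood
#'
#' Computes `p(y(t) = 1)` for every trial under a model and parameter
#' set, and the Bernoulli log-likelihood of the observed responses.
#' Missing trials contribute nothing to the sum.  Probabilities are
#' clipped to `[1e-8, 1 - 1e-8]` before taking logs; the number of
#' clipped observed trials is reported.
#'
#' @param spec a `hgfs_model_spec`.
#' @param params named list of native-space parameters.
#' @param experiment a `hgfs_experiment`.
#' @param responses a `hgfs_responses`.
#' @param trajectories optional pre-computed perceptual trajectories
#'   (recomputed from `params` when `NULL`).
#' @return list with `p` (per-trial follow probability), `loglik`,
#'   `n_clipped`, `decision` (decision trajectory or `NULL`),
#'   `trajectories`.
#' @export
likelihood_series <- function(spec, params, experiment, responses,
                              trajectories = NULL) {
  stopifnot(inherits(spec, "hgfs_model_spec"))
  n <- nrow(experiment)
  decision <- NULL
  if (spec$response == "random") {
    if (params$bias <= 0 || params$bias >= 1)
      stop("`bias` must lie in (0, 1)")
    p <- rep(params$bias, n)
  } else if (spec$response == "wsls") {
    if (params$epsilon < 0 || params$epsilon > 1)
      stop("`epsilon` must lie in [0, 1]")
    p <- vapply(seq_len(n), function(t) {
      if (t == 1L) return(0.5)
      wsls_prob_one(t, responses$chosen_card[t - 1L],
                    responses$rewarded[t - 1L],
                    experiment$gaze_target[t], params$epsilon)
    }, numeric(1))
  } else {
    if (is.null(trajectories))
      trajectories <- run_perceptual(spec, params, experiment)
    decision <- decision_trajectory(spec, trajectories, experiment, params)
    p <- decision$prob_gaze
  }
  obs <- !responses$missing
  p_clip <- pmin(pmax(p, 1e-8), 1 - 1e-8)
  n_clipped <- sum(obs & (p != p_clip))
  y <- responses$y[obs]
  loglik <- sum(y * log(p_clip[obs]) + (1 - y) * log(1 - p_clip[obs]))
  list(p = p, loglik = loglik, n_clipped = n_clipped,
       decision = decision, trajectories = trajectories)
}

#' Simulate an agent on an experiment
#'
#' Runs the perceptual filter(s) on the experiment's input series (both
#' streams are fully observable on every trial, so beliefs do not depend
#' on the agent's own choices except for the WSLS baseline), computes the
#' per-trial follow probability and samples `y(t) ~
#' Bernoulli(prob_gaze(t))`.  Pure function of
#' `(experiment, params, spec, seed)`.
#'
#' @param experiment a `hgfs_experiment`.
#' @param params named list of native-space parameters for `spec`.
#' @param spec a `hgfs_model_spec`.
#' @param seed integer seed.
#' @return list with `responses` (`hgfs_responses`), `prob_gaze`,
#'   `decision`, `trajectories`.
#' @export
simulate_agent <- function(experiment, params, spec, seed) {
  stopifnot(inherits(spec, "hgfs_model_spec"))
  if (missing(seed)) stop("a `seed` is required")
  n <- nrow(experiment)
  withr::with_seed(as.integer(seed), {
    if (spec$response == "wsls") {
      # sequential: the stay rule conditions on the agent's own history
      y <- integer(n); chosen <- character(n); rewarded <- integer(n)
      p <- numeric(n)
      for (t in seq_len(n)) {
        p[t] <- if (t == 1L) 0.5 else
          wsls_prob_one(t, chosen[t - 1L], rewarded[t - 1L],
                        experiment$gaze_target[t], params$epsilon)
        y[t] <- stats::rbinom(1L, 1L, p[t])
        chosen[t] <- if (y[t] == 1L) experiment$gaze_target[t] else
          setdiff(c("blue", "green"), experiment$gaze_target[t])
        rewarded[t] <- as.integer(chosen[t] == experiment$winning_card[t])
      }
      decision <- NULL; trajectories <- NULL
    } else if (spec$response == "random") {
      p <- rep(params$bias, n)
      y <- stats::rbinom(n, 1L, p)
      decision <- NULL; trajectories <- NULL
    } else {
      trajectories <- run_perceptual(spec, params, experiment)
      decision <- decision_trajectory(spec, trajectories, experiment, params)
      p <- decision$prob_gaze
      y <- stats::rbinom(n, 1L, p)
    }
  })
  list(responses = make_responses(y, experiment), prob_gaze = p,
       decision = decision, trajectories = trajectories)
}
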