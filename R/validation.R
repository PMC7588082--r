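#' Behavioral summary measures for one subject
#'
#' Computes the task's standard behavioral readouts over observed
#' trials:
#' \itemize{
#'   \item high-probability choices by cue and phase: for the card cue a
#'     trial counts as "high probability" when the chosen card's
#'     ground-truth winning probability is at least 0.5; for the gaze cue
#'     when the subject follows while `p_gaze >= 0.5` or declines while
#'     `p_gaze < 0.5`.  Each cue is split by its own stable/volatile
#'     phase labels.
#'   \item advice taking (proportion of followed trials) split by social
#'     accuracy (high: `p_gaze >= 0.5`) and gaze-schedule stability.
#' }
#' Cells with no observed trials are reported as `NA`.
#'
#' @param responses a `hgfs_responses`.
#' @param experiment the matching `hgfs_experiment`.
#' @param schedule the matching `hgfs_schedule`.
#' @return data.frame with columns `measure`, `cue`, `phase`,
#'   `accuracy`, `value`, `n_trials`.
#' @export
behavioral_summaries <- function(responses, experiment, schedule) {
  obs <- !responses$missing
  cell <- function(x, sel) {
    sel <- sel & obs
    data.frame(value = if (any(sel)) mean(x[sel]) else NA_real_,
               n_trials = sum(sel))
  }
  hp_card <- ifelse(responses$chosen_card == "blue",
                    schedule$p_card >= 0.5, schedule$p_card <= 0.5)
  hp_gaze <- (responses$y == 1L) == (schedule$p_gaze >= 0.5)
  acc_high <- schedule$p_gaze >= 0.5

  rows <- list()
  for (ph in c("stable", "volatile")) {
    rows[[length(rows) + 1]] <- cbind(
      data.frame(measure = "high_prob_choice", cue = "card", phase = ph,
                 accuracy = NA_character_),
      cell(hp_card, schedule$phase_card == ph))
    rows[[length(rows) + 1]] <- cbind(
      data.frame(measure = "high_prob_choice", cue = "gaze", phase = ph,
                 accuracy = NA_character_),
      cell(hp_gaze, schedule$phase_gaze == ph))
    for (acc in c("high", "low"))
      rows[[length(rows) + 1]] <- cbind(
        data.frame(measure = "advice_taking", cue = "gaze", phase = ph,
                   accuracy = acc),
        cell(responses$y,
             schedule$phase_gaze == ph & (acc_high == (acc == "high"))))
  }
  do.call(rbind, rows)
}

#' Phase-averaged precision weights
#'
#' Trial averages of the dynamic learning-rate quantities `q(psi2)` and
#' `psi3` within each stream's own stable and volatile windows.
#'
#' @param trajectories list with `card` and `gaze` `hgfs_trajectory`
#'   elements.
#' @param schedule the matching `hgfs_schedule`.
#' @return data.frame with columns `stream`, `phase`, `mean_qpsi2`,
#'   `mean_psi3`.
#' @export
precision_weight_summary <- function(trajectories, schedule) {
  rows <- list()
  for (stream in c("card", "gaze")) {
    traj <- trajectories[[stream]]
    pw <- derived_precision_weights(traj)
    phase <- schedule[[paste0("phase_", stream)]]
    for (ph in c("stable", "volatile")) {
      sel <- phase == ph
      rows[[length(rows) + 1]] <- data.frame(
        stream = stream, phase = ph,
        mean_qpsi2 = mean(pw$qpsi2[sel]),
        mean_psi3 = mean(pw$psi3[sel]))
    }
  }
  do.call(rbind, rows)
}

#' Posterior-predictive simulations
#'
#' Simulates each subject `n_rep` times on that subject's own
#' experiment from the fitted (or supplied) parameters and computes the
#' behavioral summaries of every simulated dataset.  With `n_s` subjects
#' the result holds exactly `n_s * n_rep` simulated datasets.
#'
#' @param fits list of `hgfs_fit` objects, or of lists with elements
#'   `spec` and `params_native`.
#' @param experiments list of `hgfs_experiment`, one per fit.
#' @param schedules list of `hgfs_schedule`, one per fit (or one shared
#'   schedule).
#' @param n_rep simulations per subject (default 10).
#' @param seed integer seed.
#' @return list with `runs` (one row per simulated dataset: `subject`,
#'   `rep`, wide summary columns) and `per_subject` (summaries averaged
#'   over replicates).
#' @export
posterior_predictive <- function(fits, experiments, schedules, n_rep = 10,
                                 seed = 1) {
  n_s <- length(fits)
  if (length(experiments) != n_s)
    stop("need one experiment per fit")
  if (inherits(schedules, "hgfs_schedule"))
    schedules <- rep(list(schedules), n_s)
  seeds <- derive_seeds(seed, n_s * n_rep)
  rows <- vector("list", n_s * n_rep)
  k <- 0L
  for (i in seq_len(n_s)) {
    f <- fits[[i]]
    params <- if (inherits(f, "hgfs_fit")) f$estimates_native
              else f$params_native
    spec <- f$spec
    for (r in seq_len(n_rep)) {
      k <- k + 1L
      sim <- tryCatch(
        simulate_agent(experiments[[i]], params, spec, seeds[k]),
        error = function(e)
          stop("simulation failed for subject ", i, ": ",
               conditionMessage(e)))
      summ <- behavioral_summaries(sim$responses, experiments[[i]],
                                   schedules[[i]])
      wide <- stats::setNames(summ$value,
                              paste(summ$measure, summ$cue, summ$phase,
                                    ifelse(is.na(summ$accuracy), "",
                                           summ$accuracy), sep = "."))
      rows[[k]] <- data.frame(subject = i, rep = r, t(wide))
    }
  }
  runs <- do.call(rbind, rows)
  per_subject <- stats::aggregate(
    runs[setdiff(names(runs), c("subject", "rep"))],
    by = list(subject = runs$subject), FUN = mean)
  list(runs = runs, per_subject = per_subject)
}

#' Parameter recovery
#'
#' For each subject: simulates `n_rep` response datasets from the
#' generating (true) parameters, refits the generating model to each,
#' averages the recovered estimation-space values over replicates, and
#' correlates (Pearson) the per-subject means with the generating
#' values, parameter by parameter.  Parameters with zero variance in
#' the generating values are reported as `NA` with a reason.
#'
#' @param true_params matrix or data.frame of generating values in
#'   estimation space (subjects in rows, free parameters in columns).
#' @param experiments list of `hgfs_experiment`, one per subject.
#' @param spec the generating `hgfs_model_spec`.
#' @param priors a `hgfs_priors` table for refitting.
#' @param n_rep simulations (and refits) per subject.
#' @param seed integer seed.
#' @param n_restarts optimizer restarts per refit.
#' @return object of class `hgfs_recovery`: data.frame `table`
#'   (`parameter`, `r`, `n`, `n_rep`, `note`), plus `true` and
#'   `recovered` matrices.
#' @export
parameter_recovery <- function(true_params, experiments, spec,
                               priors = default_priors(spec), n_rep = 1,
                               seed = 1, n_restarts = 2) {
  true_params <- as.matrix(true_params)
  n_s <- nrow(true_params)
  if (length(experiments) != n_s)
    stop("need one experiment per subject")
  if (n_rep < 1) stop("`n_rep` must be >= 1")
  pars <- colnames(true_params)
  seeds <- derive_seeds(seed, n_s * n_rep * 2L)
  recovered <- matrix(NA_real_, n_s, length(pars),
                      dimnames = list(NULL, pars))
  k <- 0L
  for (i in seq_len(n_s)) {
    native <- as.list(transform_parameters(true_params[i, ], priors,
                                           "to_native"))
    est <- matrix(NA_real_, n_rep, length(pars))
    for (r in seq_len(n_rep)) {
      k <- k + 1L
      sim <- simulate_agent(experiments[[i]], native, spec, seeds[2 * k - 1])
      fit <- fit_subject(experiments[[i]], sim$responses, spec,
                         priors = priors, n_restarts = n_restarts,
                         seed = seeds[2 * k])
      est[r, ] <- fit$estimates[pars]
    }
    recovered[i, ] <- colMeans(est)
  }
  tab <- do.call(rbind, lapply(pars, function(p) {
    if (stats::sd(true_params[, p]) == 0)
      data.frame(parameter = p, r = NA_real_, n = n_s, n_rep = n_rep,
                 note = "zero variance in generating values")
    else
      data.frame(parameter = p,
                 r = stats::cor(true_params[, p], recovered[, p]),
                 n = n_s, n_rep = n_rep, note = "")
  }))
  structure(list(table = tab, true = true_params, recovered = recovered),
            class = "hgfs_recovery")
}

#' @export
print.hgfs_recovery <- function(x, ...) {
  print(transform(x$table, r = round(r, 3)))
  invisible(x)
}

#' Alignment of the combined belief with the two input structures
#'
#' Simulates the combined belief `b(t)` of agents sharing perceptual
#' parameters but differing in the social weighting factor, and scores
#' how well the belief time course tracks each stream's generative
#' structure.  Because the realized gaze-frame and card-frame outcomes
#' code the same event on any given trial, alignment is measured against
#' the ground-truth schedule rather than the realized noise: agreement
#' with the gaze structure is `mean(p_gaze*b + (1-p_gaze)*(1-b))` — the
#' expected accuracy of `b` against an outcome freshly drawn from the
#' gaze schedule — and analogously for the card structure after mapping
#' `b` into the card frame.  High `zeta` aligns the belief with the
#' social structure at the expense of the non-social one.
#'
#' @param experiment a `hgfs_experiment`.
#' @param schedule the matching `hgfs_schedule`.
#' @param log_zeta_grid grid of log zeta values (default -5..5).
#' @param perceptual named list of perceptual parameters
#'   (`omega2_card`, `omega2_gaze`, `omega3_card`, `omega3_gaze`);
#'   defaults to the prior means.
#' @return data.frame with columns `log_zeta`, `agree_gaze`,
#'   `agree_card`.
#' @export
zeta_alignment <- function(experiment, schedule, log_zeta_grid = -5:5,
                           perceptual = list(omega2_card = -3,
                                             omega2_gaze = -3,
                                             omega3_card = -6,
                                             omega3_gaze = -6)) {
  spec <- model_spec("hgf", 1)
  traj <- run_perceptual(spec, perceptual, experiment)
  rows <- lapply(log_zeta_grid, function(lz) {
    params <- c(perceptual, list(zeta = exp(lz), beta = 1, eta = 0.5))
    dec <- decision_trajectory(spec, traj, experiment, params)
    b <- dec$b
    b_card_frame <- ifelse(experiment$gaze_target == "blue", b, 1 - b)
    pg <- schedule$p_gaze; pc <- schedule$p_card
    data.frame(
      log_zeta = lz,
      agree_gaze = mean(pg * b + (1 - pg) * (1 - b)),
      agree_card = mean(pc * b_card_frame + (1 - pc) * (1 - b_card_frame)))
  })
  do.call(rbind, rows)
}
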