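#' Task schedule configuration
#'
#' Defines the per-trial ground-truth probability schedules for the two
#' information streams of the probabilistic reward task: the card stream
#' (probability that the blue card wins) and the gaze stream (probability
#' that the gaze cue points at the winning card).  Each stream is described
#' by contiguous blocks of constant probability plus windows labelled
#' volatile; everything else is stable.
#'
#' The canonical 120-trial design (the default) uses the 0.73/0.27
#' probability pair.  The card contingency is stable over trials 1-60
#' (p = 0.73) and reverses three times in the volatile half (61-80: 0.27,
#' 81-100: 0.73, 101-120: 0.27).  The gaze contingency in the
#' congruent-first variant starts helpful (1-30: 0.73), reverses every ten
#' trials through the volatile window 31-70, and ends misleading
#' (71-120: 0.27); the incongruent-first variant is the pointwise mirror
#' (1 - p) of the gaze schedule.  This yields 5 gaze and 3 card
#' contingency changes.
#'
#' @param n_trials number of trials (default 120).
#' @param card_blocks,gaze_blocks data.frame or matrix with columns
#'   `start`, `end`, `p` describing constant-probability blocks that must
#'   tile `1..n_trials` without gaps or overlaps.  `NULL` selects the
#'   canonical blocks (only available for `n_trials = 120`).
#' @param variant `"congruent_first"` or `"incongruent_first"`.  Applied to
#'   the gaze stream only: the incongruent-first gaze schedule is
#'   `1 - p` pointwise.
#' @param reward_range integer vector of admissible card reward values
#'   (default `1:9`).
#' @param card_volatile,gaze_volatile two-column matrix (or vector of
#'   length 2) of trial windows labelled volatile; defaults are the
#'   canonical windows (card 61-120, gaze 31-70), clipped to `n_trials`.
#' @return an object of class `hgfs_schedule_config`.
#' @export
schedule_config <- function(n_trials = 120L,
                            card_blocks = NULL,
                            gaze_blocks = NULL,
                            variant = c("congruent_first", "incongruent_first"),
                            reward_range = 1:9,
                            card_volatile = NULL,
                            gaze_volatile = NULL) {
  variant <- match.arg(variant)
  n_trials <- as.integer(n_trials)
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials < 1L)
    stop("`n_trials` must be a single integer >= 1")
  if (!is.numeric(reward_range) || any(reward_range < 1) ||
      any(reward_range != round(reward_range)))
    stop("`reward_range` must be positive integers")

  if (is.null(card_blocks)) {
    if (n_trials != 120L)
      stop("canonical card blocks are defined for 120 trials; supply `card_blocks`")
    card_blocks <- data.frame(start = c(1L, 61L, 81L, 101L),
                              end   = c(60L, 80L, 100L, 120L),
                              p     = c(0.73, 0.27, 0.73, 0.27))
  }
  if (is.null(gaze_blocks)) {
    if (n_trials != 120L)
      stop("canonical gaze blocks are defined for 120 trials; supply `gaze_blocks`")
    gaze_blocks <- data.frame(start = c(1L, 31L, 41L, 51L, 61L, 71L),
                              end   = c(30L, 40L, 50L, 60L, 70L, 120L),
                              p     = c(0.73, 0.27, 0.73, 0.27, 0.73, 0.27))
  }
  card_blocks <- validate_blocks(card_blocks, n_trials, "card")
  gaze_blocks <- validate_blocks(gaze_blocks, n_trials, "gaze")

  if (is.null(card_volatile)) card_volatile <- c(61L, 120L)
  if (is.null(gaze_volatile)) gaze_volatile <- c(31L, 70L)
  card_volatile <- validate_windows(card_volatile, n_trials)
  gaze_volatile <- validate_windows(gaze_volatile, n_trials)

  structure(list(n_trials = n_trials, card_blocks = card_blocks,
                 gaze_blocks = gaze_blocks, variant = variant,
                 reward_range = as.integer(reward_range),
                 card_volatile = card_volatile, gaze_volatile = gaze_volatile),
            class = "hgfs_schedule_config")
}

validate_blocks <- function(blocks, n_trials, stream) {
  blocks <- as.data.frame(blocks)
  if (!all(c("start", "end", "p") %in% names(blocks)))
    stop("blocks need columns `start`, `end`, `p`")
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  if (any(blocks$p < 0 | blocks$p > 1))
    stop(sprintf("%s block probabilities must lie in [0,1]", stream))
  covered <- integer(0)
  for (i in seq_len(nrow(blocks))) {
    rng <- seq.int(blocks$start[i], blocks$end[i])
    if (any(rng %in% covered))
      stop(sprintf("%s blocks overlap at trials %d-%d", stream,
                   blocks$start[i], blocks$end[i]))
    covered <- c(covered, rng)
  }
  missing <- setdiff(seq_len(n_trials), covered)
  if (length(missing) || length(setdiff(covered, seq_len(n_trials))))
    stop(sprintf("%s blocks do not tile 1..%d (problem near trial %d)",
                 stream, n_trials,
                 if (length(missing)) missing[1] else max(covered)))
  blocks
}

validate_windows <- function(w, n_trials) {
  w <- matrix(as.integer(w), ncol = 2, byrow = FALSE)
  if (any(w[, 1] > w[, 2]) || any(w < 1) || any(w > n_trials))
    stop("volatile windows must satisfy 1 <= start <= end <= n_trials")
  w
}

#' Build a per-trial task schedule
#'
#' Expands a [schedule_config()] into per-trial probability series and
#' stable/volatile phase labels for both streams.  For the
#' incongruent-first variant the gaze probabilities are mirrored
#' (`1 - p`); phase labels are unaffected by the variant.
#'
#' @param config a `hgfs_schedule_config` (default: canonical
#'   congruent-first design).
#' @return a data.frame of class `hgfs_schedule` with columns `trial`,
#'   `p_card`, `p_gaze`, `phase_card`, `phase_gaze` (factors with levels
#'   stable/volatile).
#' @export
#' @examples
#' sch <- build_schedule(schedule_config())
#' table(sch$phase_gaze)
build_schedule <- function(config = schedule_config()) {
  stopifnot(inherits(config, "hgfs_schedule_config"))
  n <- config$n_trials
  expand <- function(blocks) {
    p <- rep(NA_real_, n)
    for (i in seq_len(nrow(blocks)))
      p[blocks$start[i]:blocks$end[i]] <- blocks$p[i]
    p
  }
  p_card <- expand(config$card_blocks)
  p_gaze <- expand(config$gaze_blocks)
  if (config$variant == "incongruent_first") p_gaze <- 1 - p_gaze

  phase_of <- function(windows) {
    ph <- rep("stable", n)
    for (i in seq_len(nrow(windows)))
      ph[windows[i, 1]:windows[i, 2]] <- "volatile"
    factor(ph, levels = c("stable", "volatile"))
  }
  out <- data.frame(trial = seq_len(n), p_card = p_card, p_gaze = p_gaze,
                    phase_card = phase_of(config$card_volatile),
                    phase_gaze = phase_of(config$gaze_volatile))
  attr(out, "variant") <- config$variant
  attr(out, "reward_range") <- config$reward_range
  class(out) <- c("hgfs_schedule", "data.frame")
  out
}

#' Count contingency changes in a schedule
#'
#' A contingency change is any trial `t >= 2` at which the ground-truth
#' probability of the chosen stream differs from trial `t - 1`.  The
#' canonical design has 5 gaze and 3 card changes, making the social cue
#' the more volatile source of information.
#'
#' @param schedule a `hgfs_schedule`.
#' @param stream `"card"` or `"gaze"`.
#' @return integer count.
#' @export
count_contingency_changes <- function(schedule, stream = c("card", "gaze")) {
  stream <- match.arg(stream)
  p <- schedule[[paste0("p_", stream)]]
  if (is.null(p)) stop("schedule lacks probability column for stream ", stream)
  sum(diff(p) != 0)
}
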