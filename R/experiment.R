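#' Sample one subject's experimental inputs from a schedule
#'
#' Draws the realized binary outcome series of one run of the task:
#' `u_card(t) ~ Bernoulli(p_card(t))` (1 = blue wins) and, independently,
#' `u_gaze(t) ~ Bernoulli(p_gaze(t))` (1 = gaze points at the winning
#' card).  The gaze target is derived (the winning card when the gaze is
#' correct, the other card otherwise) and each card carries an independent
#' uniform integer reward from the schedule's reward range.  The function
#' is a pure function of `(schedule, seed)`.
#'
#' @param schedule a `hgfs_schedule` from [build_schedule()].
#' @param seed integer seed.
#' @return data.frame of class `hgfs_experiment`, one row per trial, with
#'   columns `trial`, `winning_card`, `u_card`, `u_gaze`, `gaze_target`,
#'   `reward_blue`, `reward_green`, `r_gaze`, `r_notgaze`.
#' @export
generate_experiment <- function(schedule, seed) {
  stopifnot(inherits(schedule, "hgfs_schedule"))
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer `seed` is required")
  rr <- attr(schedule, "reward_range")
  if (is.null(rr)) rr <- 1:9
  n <- nrow(schedule)
  withr::with_seed(as.integer(seed), {
    u_card <- stats::rbinom(n, 1L, schedule$p_card)
    u_gaze <- stats::rbinom(n, 1L, schedule$p_gaze)
    reward_blue <- sample(rr, n, replace = TRUE)
    reward_green <- sample(rr, n, replace = TRUE)
  })
  winning_card <- ifelse(u_card == 1L, "blue", "green")
  other_card <- ifelse(u_card == 1L, "green", "blue")
  gaze_target <- ifelse(u_gaze == 1L, winning_card, other_card)
  r_gaze <- ifelse(gaze_target == "blue", reward_blue, reward_green)
  r_notgaze <- ifelse(gaze_target == "blue", reward_green, reward_blue)
  out <- data.frame(trial = seq_len(n), winning_card = winning_card,
                    u_card = as.integer(u_card), u_gaze = as.integer(u_gaze),
                    gaze_target = gaze_target,
                    reward_blue = as.integer(reward_blue),
                    reward_green = as.integer(reward_green),
                    r_gaze = as.integer(r_gaze),
                    r_notgaze = as.integer(r_notgaze))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "reward_range") <- rr
  class(out) <- c("hgfs_experiment", "data.frame")
  out
}

#' Derive a response record from follow/not-follow choices
#'
#' Responses are coded in the gaze frame (`y = 1` means the subject chose
#' the card the gaze pointed at).  The chosen card and reward indicator
#' are derived from the experiment's gaze target and winning card.
#'
#' @param y integer vector in `{0, 1}` (NA allowed for missed trials).
#' @param experiment the matching `hgfs_experiment`.
#' @return data.frame of class `hgfs_responses` with columns `trial`, `y`,
#'   `chosen_card`, `rewarded`, `missing`.
#' @export
make_responses <- function(y, experiment) {
  stopifnot(inherits(experiment, "hgfs_experiment"))
  n <- nrow(experiment)
  if (length(y) != n) stop("`y` must have one entry per trial")
  if (!all(y %in% c(0L, 1L, NA)))
    stop("`y` must be binary (0 = not follow, 1 = follow) or NA")
  y <- as.integer(y)
  other <- ifelse(experiment$gaze_target == "blue", "green", "blue")
  chosen <- ifelse(is.na(y), NA_character_,
                   ifelse(y == 1L, experiment$gaze_target, other))
  rewarded <- ifelse(is.na(y), NA_integer_,
                     as.integer(chosen == experiment$winning_card))
  out <- data.frame(trial = seq_len(n), y = y, chosen_card = chosen,
                    rewarded = rewarded, missing = is.na(y))
  class(out) <- c("hgfs_responses", "data.frame")
  out
}

TRIAL_TABLE_COLUMNS <- c("trial", "winning_card", "u_card", "u_gaze",
                         "gaze_target", "reward_blue", "reward_green",
                         "y", "chosen_card", "rewarded", "missing")

#' Write a trial table to CSV
#'
#' One row per trial, UTF-8 comma-separated with a header row; columns
#' `trial, winning_card, u_card, u_gaze, gaze_target, reward_blue,
#' reward_green, y, chosen_card, rewarded, missing`.  Missed trials carry
#' `NA` in the response columns and `missing = TRUE`.
#'
#' @param experiment a `hgfs_experiment`.
#' @param responses optional matching `hgfs_responses`; if `NULL` the
#'   response columns are written as `NA`/`TRUE`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(experiment, responses = NULL, path) {
  stopifnot(inherits(experiment, "hgfs_experiment"))
  n <- nrow(experiment)
  if (is.null(responses))
    responses <- make_responses(rep(NA_integer_, n), experiment)
  tab <- cbind(experiment[c("trial", "winning_card", "u_card", "u_gaze",
                            "gaze_target", "reward_blue", "reward_green")],
               responses[c("y", "chosen_card", "rewarded", "missing")])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Reconstructs the experiment and response objects written by
#' [write_trial_table()]; `read(write(x))` is the identity on all fields.
#' Rows with a missing response are tolerated and flagged.
#'
#' @param path CSV file path.
#' @return list with elements `experiment` (`hgfs_experiment`) and
#'   `responses` (`hgfs_responses`).
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(TRIAL_TABLE_COLUMNS, names(tab))
  if (length(missing_cols))
    stop("trial table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!all(tab$y %in% c(0L, 1L, NA)))
    stop("column `y` must be binary (0/1) or empty")
  if (!all(tab$u_card %in% c(0L, 1L)) || !all(tab$u_gaze %in% c(0L, 1L)))
    stop("columns `u_card`/`u_gaze` must be binary (0/1)")
  exp_cols <- c("trial", "winning_card", "u_card", "u_gaze", "gaze_target",
                "reward_blue", "reward_green")
  experiment <- tab[exp_cols]
  experiment$r_gaze <- ifelse(experiment$gaze_target == "blue",
                              experiment$reward_blue, experiment$reward_green)
  experiment$r_notgaze <- ifelse(experiment$gaze_target == "blue",
                                 experiment$reward_green, experiment$reward_blue)
  class(experiment) <- c("hgfs_experiment", "data.frame")
  responses <- make_responses(tab$y, experiment)
  list(experiment = experiment, responses = responses)
}
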