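#' @useDynLib socialrl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate cor cor.test dbeta dgamma dnbinom dnorm optim
#'   plogis pnorm qlogis qnorm rbeta rgamma rnorm runif sd setNames t.test var
#' @importFrom utils read.csv write.csv
NULL

# ---- conditions -------------------------------------------------------------

#' Task conditions
#'
#' The three learning contexts of the task: `"private"` (no social
#' information), `"social_choice"` (the demonstrator's choice is displayed)
#' and `"social_choice_outcome"` (choice and outcome are displayed).
#'
#' @return Character vector of the three condition labels, in canonical order.
#' @export
conditions <- function() {
  c("private", "social_choice", "social_choice_outcome")
}

# internal integer coding used by the C++ kernel
condition_code <- function(condition) {
  code <- match(condition, conditions()) - 1L
  if (anyNA(code)) stop("unknown condition label", call. = FALSE)
  code
}

contingencies <- function() c("stable_30_70", "reversal_20_80")

# ---- configuration ----------------------------------------------------------

#' Task configuration
#'
#' Describes one experiment: six blocks (each condition crossed with a stable
#' and a reversal contingency), 20 trials per block, rewards of +1/-1 points.
#' In stable blocks the reciprocal reward probabilities are 30/70% throughout;
#' in reversal blocks they are 20/80% and swap between the two options at a
#' reversal trial drawn uniformly from `reversal_window` (0-based; the swap
#' applies from that trial onward).
#'
#' @param n_trials Trials per block (default 20).
#' @param p_stable Reward probability pair (option 0, option 1) for stable
#'   blocks; must be reciprocal (sum to 1), entries in (0, 1).
#' @param p_reversal Reward probability pair for reversal blocks before the
#'   reversal; same constraints.
#' @param reversal_window Integer vector of admissible 0-based reversal trial
#'   indices (default `9:11`, i.e. around the 10th trial).
#' @param points_per_dollar Points-to-money conversion, kept as metadata only.
#' @return A list of class `"task_config"`.
#' @export
task_config <- function(n_trials = 20L, p_stable = c(0.7, 0.3),
                        p_reversal = c(0.8, 0.2), reversal_window = 9:11,
                        points_per_dollar = 40) {
  n_trials <- as.integer(n_trials)
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials < 1L)
    stop("`n_trials` must be a positive integer", call. = FALSE)
  for (p in list(p_stable, p_reversal)) {
    if (length(p) != 2L || any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
      stop("reward probabilities must lie strictly inside (0, 1)",
           call. = FALSE)
    if (abs(sum(p) - 1) > 1e-12)
      stop("reward probabilities must be reciprocal (sum to 1)",
           call. = FALSE)
  }
  reversal_window <- as.integer(reversal_window)
  if (any(reversal_window < 1L) || any(reversal_window >= n_trials))
    stop("reversal window infeasible for `n_trials` (a reversal must leave ",
         "trials on both sides of it)", call. = FALSE)
  structure(list(n_trials = n_trials, p_stable = p_stable,
                 p_reversal = p_reversal, reversal_window = reversal_window,
                 points_per_dollar = points_per_dollar),
            class = "task_config")
}

# ---- schedule ---------------------------------------------------------------

#' Build a randomized experiment schedule
#'
#' Creates the six-block schedule: each condition appears exactly once with
#' stable contingencies and once with reversal contingencies, in uniformly
#' random order. Reversal trials are drawn uniformly from the configured
#' window. Internally option 0 is always the initially better option; display
#' randomization is outside the model.
#'
#' Uses the current RNG state; call [set.seed()] beforehand for
#' reproducibility.
#'
#' @param config A [task_config()].
#' @return A data frame of class `"experiment_schedule"` with one row per
#'   block and columns `block_id`, `condition`, `contingency`, `p0` (initial
#'   reward probability of option 0), `reversal_trial` (`NA` for stable
#'   blocks) and `n_trials`.
#' @export
build_schedule <- function(config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  grid <- expand.grid(condition = conditions(),
                      contingency = contingencies(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ord <- sample.int(nrow(grid))
  grid <- grid[ord, , drop = FALSE]
  rev_trial <- ifelse(
    grid$contingency == "reversal_20_80",
    config$reversal_window[sample.int(length(config$reversal_window),
                                      nrow(grid), replace = TRUE)],
    NA_integer_)
  out <- data.frame(
    block_id = seq_len(nrow(grid)),
    condition = grid$condition,
    contingency = grid$contingency,
    p0 = ifelse(grid$contingency == "stable_30_70",
                config$p_stable[1], config$p_reversal[1]),
    reversal_trial = as.integer(rev_trial),
    n_trials = config$n_trials,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("experiment_schedule", "data.frame")
  out
}

#' Scheduled reward probability of an option at a given trial
#'
#' @param block One row of an [build_schedule()] schedule (data frame row or
#'   list with `p0`, `reversal_trial`, `n_trials`).
#' @param t 0-based trial index within the block.
#' @param option Option index (0 or 1).
#' @return The probability that the option yields +1 at trial `t`.
#' @export
scheduled_p <- function(block, t, option = 0L) {
  if (any(t < 0L) || any(t >= block$n_trials))
    stop("trial index out of range", call. = FALSE)
  if (!all(option %in% c(0L, 1L))) stop("option must be 0 or 1", call. = FALSE)
  rev <- block$reversal_trial
  p0 <- ifelse(!is.na(rev) & t >= rev, 1 - block$p0, block$p0)
  ifelse(option == 0L, p0, 1 - p0)
}

#' Draw a reward outcome
#'
#' Samples a +1/-1 outcome for choosing `choice` at trial `t` of a block,
#' honouring the block's reversal if any. Uses the current RNG state.
#'
#' @inheritParams scheduled_p
#' @param choice Chosen option (0 or 1).
#' @return `+1` or `-1`.
#' @export
draw_outcome <- function(block, t, choice) {
  p <- scheduled_p(block, t, choice)
  ifelse(runif(length(p)) < p, 1, -1)
}

# ---- trial log I/O ----------------------------------------------------------

trial_columns <- c("subject_id", "block_id", "condition", "contingency",
                   "trial", "participant_choice", "participant_outcome",
                   "demonstrator_choice", "demonstrator_outcome", "correct")

#' Write / read trial logs
#'
#' Trial logs are plain CSV with columns `subject_id, block_id, condition,
#' contingency, trial, participant_choice, participant_outcome,
#' demonstrator_choice, demonstrator_outcome, correct`; social fields are
#' empty for private blocks.
#'
#' @param trials A trial-log data frame (e.g. `sessions` from
#'   [generate_cohort()] or the output of [simulate_participant()]).
#' @param file Path to the CSV file.
#' @return `read_trials()` returns the trial-log data frame;
#'   `write_trials()` returns `file` invisibly.
#' @export
write_trials <- function(trials, file) {
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols) > 0)
    stop("trial log lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  write.csv(trials[, trial_columns], file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_trials
#' @export
read_trials <- function(file) {
  out <- read.csv(file, stringsAsFactors = FALSE,
                  colClasses = c(subject_id = "character"))
  out$correct <- as.logical(out$correct)
  out
}
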