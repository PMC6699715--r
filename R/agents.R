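# ---- parameters -------------------------------------------------------------

#' Social reinforcement-learning parameters
#'
#' The six free parameters of the social RL model. Private blocks are played
#' as a plain Q-learner with temperature `beta_p` and learning rate
#' `alpha_p`. Both social conditions use their own private-learning pair
#' (`beta_s`, `alpha_s`). In the social-choice condition the demonstrator's
#' previous choice additionally biases the choice probability with imitation
#' rate `kappa`; in the social-choice+outcome condition the demonstrator's
#' outcome drives a vicarious value update with observational learning rate
#' `alpha_o`.
#'
#' @param beta_p,beta_s Softmax temperatures, > 0.
#' @param alpha_p,alpha_s,kappa,alpha_o Rates in \[0, 1\].
#' @return A named numeric vector of class `"social_rl_params"` in the order
#'   `beta_p, alpha_p, beta_s, alpha_s, kappa, alpha_o`.
#' @export
social_rl_params <- function(beta_p, alpha_p, beta_s, alpha_s, kappa,
                             alpha_o) {
  p <- c(beta_p = beta_p, alpha_p = alpha_p, beta_s = beta_s,
         alpha_s = alpha_s, kappa = kappa, alpha_o = alpha_o)
  if (any(!is.finite(p))) stop("parameters must be finite", call. = FALSE)
  if (beta_p < 0 || beta_s < 0)
    stop("temperatures must be non-negative", call. = FALSE)
  rates <- p[c("alpha_p", "alpha_s", "kappa", "alpha_o")]
  if (any(rates < 0 | rates > 1))
    stop("rate parameters must lie in [0, 1]", call. = FALSE)
  structure(p, class = "social_rl_params")
}

#' Names of the six social RL parameters, in canonical order
#' @return Character vector of length 6.
#' @export
param_names <- function() {
  c("beta_p", "alpha_p", "beta_s", "alpha_s", "kappa", "alpha_o")
}

#' Demonstrator (plain Q-learner) parameters
#'
#' The simulated demonstrator plays every block as an ordinary Q-learner,
#' learning only from its own outcomes. Defaults follow the generative
#' settings used for the virtual partner: learning rate 0.5 and temperature
#' 10.
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Softmax temperature, > 0.
#' @return Named numeric vector of class `"demonstrator_params"`.
#' @export
demonstrator_params <- function(alpha = 0.5, beta = 10) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (beta < 0) stop("beta must be non-negative", call. = FALSE)
  structure(c(alpha = alpha, beta = beta), class = "demonstrator_params")
}

# map a plain Q-learner (alpha, beta) onto the 6-parameter vector; with
# kappa = alpha_o = 0 and shared alpha/beta the social kernel reduces exactly
# to ordinary Q-learning in every condition
qlearn_as_social <- function(alpha, beta) {
  c(beta_p = beta, alpha_p = alpha, beta_s = beta, alpha_s = alpha,
    kappa = 0, alpha_o = 0)
}

# ---- elementary model operations -------------------------------------------

#' Softmax choice probabilities
#'
#' Two-option logistic softmax: `P(a) = 1 / (1 + exp(-beta * (q[a] - q[b])))`.
#'
#' @param q Numeric pair of action values.
#' @param beta Temperature, >= 0 (0 gives 0.5/0.5).
#' @return Probability pair over the two options (sums to 1).
#' @export
choice_prob <- function(q, beta) {
  stopifnot(length(q) == 2L, is.finite(q))
  if (!is.finite(beta) || beta < 0)
    stop("beta must be non-negative", call. = FALSE)
  p0 <- 1 / (1 + exp(-beta * (q[1] - q[2])))
  c(p0, 1 - p0)
}

#' Reward prediction error
#'
#' @param q_chosen Current value of the chosen option.
#' @param r Received reward (+1 or -1).
#' @return `r - q_chosen`.
#' @export
rpe <- function(q_chosen, r) {
  r - q_chosen
}

#' Delta-rule value update
#'
#' Moves the chosen option's value toward the received reward by a fraction
#' `alpha`; the unchosen value is untouched.
#'
#' @param q Numeric pair of action values.
#' @param choice Chosen option (0 or 1).
#' @param r Reward.
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated value pair.
#' @export
q_update <- function(q, choice, r, alpha) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)
  stopifnot(choice %in% c(0L, 1L))
  i <- choice + 1L
  q[i] <- q[i] + alpha * rpe(q[i], r)
  q
}

#' Action prediction error
#'
#' Surprise about the demonstrator's choice: 1 minus the probability the
#' observer's current policy assigned to it.
#'
#' @param p_dem_action Probability in \[0, 1\].
#' @return `1 - p_dem_action`.
#' @export
action_pe <- function(p_dem_action) {
  if (!is.finite(p_dem_action) || p_dem_action < 0 || p_dem_action > 1)
    stop("probability must lie in [0, 1]", call. = FALSE)
  1 - p_dem_action
}

#' Imitation bias on choice probabilities
#'
#' Shifts probability toward the demonstrator's observed choice:
#' `P'(dem) = P(dem) + kappa * (1 - P(dem))`, the other option renormalized.
#' Closed in \[0, 1\]; no clipping needed.
#'
#' @param p Probability pair (sums to 1).
#' @param dem_choice Demonstrator's chosen option (0 or 1).
#' @param kappa Imitation rate in \[0, 1\].
#' @return Biased probability pair.
#' @export
apply_imitation <- function(p, dem_choice, kappa) {
  if (!is.finite(kappa) || kappa < 0 || kappa > 1)
    stop("kappa must lie in [0, 1]", call. = FALSE)
  stopifnot(length(p) == 2L, abs(sum(p) - 1) < 1e-9,
            dem_choice %in% c(0L, 1L))
  i <- dem_choice + 1L
  p[i] <- p[i] + kappa * action_pe(p[i])
  p[3L - i] <- 1 - p[i]
  p
}

#' Observational (vicarious) value update
#'
#' Updates the value of the demonstrator's chosen option toward the
#' demonstrator's outcome with rate `alpha_o`.
#'
#' @param q Numeric pair of action values.
#' @param dem_choice Demonstrator's chosen option (0 or 1).
#' @param r_dem Demonstrator's reward.
#' @param alpha_o Observational learning rate in \[0, 1\].
#' @return Updated value pair.
#' @export
observational_update <- function(q, dem_choice, r_dem, alpha_o) {
  q_update(q, dem_choice, r_dem, alpha_o)
}

# ---- simulators -------------------------------------------------------------

schedule_kernel_args <- function(schedule) {
  list(n_trials = as.integer(schedule$n_trials),
       cond = condition_code(schedule$condition),
       pr0 = as.numeric(schedule$p0),
       rev = ifelse(is.na(schedule$reversal_trial), -1L,
                    as.integer(schedule$reversal_trial)))
}

#' Simulate the demonstrator's session
#'
#' The demonstrator plays every block of the schedule as a plain Q-learner
#' (values reset to 0 at each block start), learning only from its own
#' outcomes. Uses the current RNG state.
#'
#' @param schedule An [build_schedule()] schedule.
#' @param params [demonstrator_params()].
#' @return Data frame with columns `block_id`, `trial`, `choice`, `outcome`.
#' @export
simulate_demonstrator <- function(schedule, params = demonstrator_params()) {
  a <- schedule_kernel_args(schedule)
  out <- cpp_simulate_demonstrator(a$n_trials, a$pr0, a$rev,
                                   params[["alpha"]], params[["beta"]])
  out$block_id <- schedule$block_id[out$block_id]
  as.data.frame(out)
}

#' Simulate a participant session
#'
#' Plays the full schedule under the social RL model. Private blocks use
#' (`alpha_p`, `beta_p`) and plain Q-learning. Social-choice blocks use
#' (`alpha_s`, `beta_s`) plus the imitation bias toward the demonstrator's
#' most recently displayed choice (no bias on a block's first trial).
#' Social-choice+outcome blocks use (`alpha_s`, `beta_s`) plus the
#' observational update from the displayed demonstrator outcome; the
#' imitation bias is not applied there. Within a trial the participant
#' chooses first; the demonstrator's trial-t information affects trial t+1.
#' Values reset to 0 at each block start. Uses the current RNG state.
#'
#' @param schedule An [build_schedule()] schedule.
#' @param dem Demonstrator stream from [simulate_demonstrator()], aligned
#'   with `schedule` (required whenever the schedule contains social blocks).
#' @param params [social_rl_params()].
#' @param subject_id Identifier written into the trial log.
#' @return A trial-log data frame (one row per trial) with the standard
#'   columns plus `logp_choice`, the log probability the model assigned to
#'   the emitted choice.
#' @export
simulate_participant <- function(schedule, dem, params,
                                 subject_id = "s1") {
  a <- schedule_kernel_args(schedule)
  social <- a$cond != 0L
  if (any(social) && (missing(dem) || is.null(dem)))
    stop("demonstrator stream required for social blocks", call. = FALSE)
  if (missing(dem) || is.null(dem)) {
    dem <- list(choice = rep(-1L, sum(a$n_trials)),
                outcome = rep(0, sum(a$n_trials)))
  }
  if (length(dem$choice) != sum(a$n_trials))
    stop("demonstrator stream not aligned with schedule", call. = FALSE)
  if (!is.null(names(params)) && all(param_names() %in% names(params)))
    params <- params[param_names()]
  out <- cpp_simulate_participant(a$n_trials, a$cond, a$pr0, a$rev,
                                  as.integer(dem$choice),
                                  as.numeric(dem$outcome),
                                  as.numeric(params), 1e-9)
  b <- out$block_id
  trials <- data.frame(
    subject_id = subject_id,
    block_id = schedule$block_id[b],
    condition = schedule$condition[b],
    contingency = schedule$contingency[b],
    trial = out$trial,
    participant_choice = out$choice,
    participant_outcome = out$outcome,
    demonstrator_choice = ifelse(a$cond[b] == 0L, NA_integer_, dem$choice),
    demonstrator_outcome = ifelse(a$cond[b] == 2L, dem$outcome, NA_real_),
    correct = out$correct,
    logp_choice = out$logp_choice,
    stringsAsFactors = FALSE)
  trials
}

#' Simulate one full session (schedule + demonstrator + participant)
#'
#' Convenience wrapper: builds a fresh schedule, simulates a demonstrator on
#' it, then the participant. Uses the current RNG state.
#'
#' @inheritParams simulate_participant
#' @param config A [task_config()].
#' @param dem_params [demonstrator_params()].
#' @return Trial-log data frame as in [simulate_participant()].
#' @export
simulate_session <- function(params, config = task_config(),
                             dem_params = demonstrator_params(),
                             subject_id = "s1") {
  schedule <- build_schedule(config)
  dem <- simulate_demonstrator(schedule, dem_params)
  simulate_participant(schedule, dem, params, subject_id = subject_id)
}
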