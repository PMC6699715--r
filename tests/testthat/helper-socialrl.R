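# shared fixtures built in code

mid_params <- function() {
  social_rl_params(beta_p = 2, alpha_p = 0.5, beta_s = 2, alpha_s = 0.55,
                   kappa = 0.2, alpha_o = 0.4)
}

# a reproducible single-subject session with demonstrator streams
toy_session <- function(seed = 42, params = mid_params(),
                        config = task_config()) {
  withr::with_seed(seed, simulate_session(params, config))
}

# R-level replay of the social RL policy using only the exported scalar
# operations; independent of the compiled likelihood path. Returns per-trial
# probability pairs and log-probabilities of the recorded choices.
replay_session <- function(trials, params) {
  trials <- trials[order(trials$block_id, trials$trial), , drop = FALSE]
  n <- nrow(trials)
  logp <- numeric(n)
  probs <- matrix(NA_real_, n, 2)
  qmat <- matrix(NA_real_, n, 2)
  q <- c(0, 0)
  last_dem <- NA_integer_
  for (i in seq_len(n)) {
    if (trials$trial[i] == 0) {
      q <- c(0, 0)
      last_dem <- NA_integer_
    }
    cond <- trials$condition[i]
    beta <- if (cond == "private") params[["beta_p"]] else params[["beta_s"]]
    p <- choice_prob(q, beta)
    if (cond == "social_choice" && !is.na(last_dem))
      p <- apply_imitation(p, last_dem, params[["kappa"]])
    ch <- trials$participant_choice[i]
    probs[i, ] <- p
    logp[i] <- log(max(p[ch + 1], 1e-9))
    alpha <- if (cond == "private") params[["alpha_p"]] else
      params[["alpha_s"]]
    q <- q_update(q, ch, trials$participant_outcome[i], alpha)
    if (cond == "social_choice") last_dem <- trials$demonstrator_choice[i]
    if (cond == "social_choice_outcome")
      q <- observational_update(q, trials$demonstrator_choice[i],
                                trials$demonstrator_outcome[i],
                                params[["alpha_o"]])
    qmat[i, ] <- q
  }
  list(logp = logp, probs = probs, q = qmat)
}
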