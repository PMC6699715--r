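test_that("softmax, prediction errors and updates follow the model equations", {
  expect_equal(choice_prob(c(0.3, -0.2), 0), c(0.5, 0.5))
  expect_gt(choice_prob(c(1, -1), 50)[1], 1 - 1e-10)
  expect_equal(choice_prob(c(0.5, 0), 2)[1], 1 / (1 + exp(-1)))
  expect_equal(sum(choice_prob(c(0.37, -0.81), 3.2)), 1)
  expect_error(choice_prob(c(0, 0), -1), "non-negative")

  expect_equal(rpe(0, 1), 1)
  expect_equal(rpe(1, 1), 0)
  expect_equal(rpe(0.4, -1), -1.4)

  expect_equal(q_update(c(0, 0), 0L, 1, 0.5), c(0.5, 0))
  expect_equal(q_update(c(0.3, -0.1), 1L, 1, 0), c(0.3, -0.1))
  expect_equal(q_update(c(0.3, -0.1), 1L, -1, 1)[2], -1)
  expect_error(q_update(c(0, 0), 0L, 1, 1.5), "0, 1")

  expect_equal(action_pe(1), 0)
  expect_equal(action_pe(0), 1)
  expect_equal(action_pe(0.4), 0.6)
  expect_error(action_pe(1.2), "0, 1")

  expect_equal(apply_imitation(c(0.6, 0.4), 1L, 0), c(0.6, 0.4))
  expect_equal(apply_imitation(c(0.6, 0.4), 1L, 1), c(0, 1))
  expect_equal(apply_imitation(c(0.6, 0.4), 1L, 0.5), c(0.3, 0.7))
  expect_error(apply_imitation(c(0.6, 0.4), 1L, 2), "0, 1")

  expect_equal(observational_update(c(0.2, 0), 1L, -1, 0.46)[2], -0.46)
  expect_equal(observational_update(c(0.2, 0), 0L, 1, 0), c(0.2, 0))
})

test_that("imitation bias is monotone in kappa and repeated vicarious
          updates converge to the observed reward", {
  p <- c(0.4, 0.6)
  biased <- vapply(seq(0, 1, by = 0.1),
                   function(k) apply_imitation(p, 0L, k)[1], numeric(1))
  expect_true(all(diff(biased) > 0))
  expect_true(all(biased >= 0 & biased <= 1))

  q <- c(0, 0)
  path <- numeric(30)
  for (i in 1:30) {
    q <- observational_update(q, 0L, 1, 0.3)
    path[i] <- q[1]
  }
  expect_true(all(diff(path) > 0))
  expect_equal(path[30], 1, tolerance = 1e-4)
})

test_that("simulated sessions keep probabilities and values in bounds", {
  for (seed in 1:8) {
    pars <- withr::with_seed(seed * 100, social_rl_params(
      runif(1, 0.1, 15), runif(1), runif(1, 0.1, 15), runif(1), runif(1),
      runif(1)))
    tr <- toy_session(seed, pars)
    rp <- replay_session(tr, pars)
    expect_true(all(rp$probs >= 0 & rp$probs <= 1))
    expect_equal(rowSums(rp$probs), rep(1, nrow(tr)))
    expect_true(all(abs(rp$q) <= 1))
    expect_true(all(tr$participant_outcome %in% c(-1, 1)))
  }
})

test_that("the compiled likelihood matches an R replay through the exported
          scalar operations", {
  for (seed in c(3, 14)) {
    pars <- mid_params()
    tr <- toy_session(seed, pars)
    rp <- replay_session(tr, pars)
    expect_identical(tr$logp_choice, rp$logp)
    expect_identical(as.numeric(session_loglik(pars, tr, "social")),
                     sum(rp$logp))
  }
})

test_that("neutral social parameters reduce the model to plain Q-learning", {
  pars <- social_rl_params(beta_p = 2.5, alpha_p = 0.4, beta_s = 2.5,
                           alpha_s = 0.4, kappa = 0, alpha_o = 0)
  tr <- toy_session(5, pars)
  expect_identical(
    as.numeric(session_loglik(pars, tr, "social")),
    as.numeric(session_loglik(c(alpha = 0.4, beta = 2.5), tr, "qlearn")))
})

test_that("kappa = 1 makes the participant copy the demonstrator's previous
          choice in social-choice blocks", {
  pars <- social_rl_params(2, 0.5, 2, 0.5, kappa = 1, alpha_o = 0)
  tr <- toy_session(9, pars)
  sc <- tr[tr$condition == "social_choice" & tr$trial > 0, ]
  dem_prev <- tr$demonstrator_choice[match(
    paste(sc$block_id, sc$trial - 1), paste(tr$block_id, tr$trial))]
  expect_identical(sc$participant_choice, dem_prev)
})

test_that("demonstrator learns the task and degenerates to chance at beta=0", {
  cfg <- task_config()
  correct_curve <- function(beta, n_blocks = 300) {
    withr::with_seed(17, {
      hits <- matrix(NA_real_, n_blocks, cfg$n_trials)
      sch <- data.frame(block_id = 1L, condition = "private",
                        contingency = "stable_30_70", p0 = 0.7,
                        reversal_trial = NA_integer_,
                        n_trials = cfg$n_trials)
      class(sch) <- c("experiment_schedule", "data.frame")
      for (b in seq_len(n_blocks)) {
        d <- simulate_demonstrator(sch, demonstrator_params(beta = beta))
        hits[b, ] <- as.numeric(d$choice == 0L)
      }
      colMeans(hits)
    })
  }
  curve <- correct_curve(10)
  expect_lt(mean(curve[1:3]), mean(curve[16:20]))
  expect_gt(mean(curve[16:20]), 0.7)
  expect_lt(mean(curve[16:20]), 0.95)
  flat <- correct_curve(0, n_blocks = 150)
  expect_equal(mean(flat), 0.5, tolerance = 0.05 / 0.5)
})

test_that("participant simulation is deterministic under a seed and demands
          a demonstrator for social blocks", {
  expect_identical(toy_session(33), toy_session(33))
  sch <- withr::with_seed(2, build_schedule())
  expect_error(simulate_participant(sch, NULL, mid_params()),
               "demonstrator stream")
})

test_that("good demonstrators raise participant performance in social
          conditions only", {
  n <- 200
  rates <- withr::with_seed(77, {
    out <- matrix(NA_real_, n, 6)
    for (i in seq_len(n)) {
      sch <- build_schedule()
      dem <- simulate_demonstrator(sch)
      tr <- simulate_participant(sch, dem, mid_params())
      dem_correct <- tr$correct  # participant-side flags
      # demonstrator correct rate per session
      dc <- mean((dem$choice == 0) == (scheduled_p(
        sch[match(dem$block_id, sch$block_id), ], dem$trial, 0L) >= 0.5))
      cr <- correct_rates(tr)
      out[i, ] <- c(dc, cr$private, cr$social_choice,
                    cr$social_choice_outcome, NA, NA)
    }
    out
  })
  r_priv <- cor(rates[, 1], rates[, 2])
  r_sc <- cor(rates[, 1], rates[, 3])
  r_sco <- cor(rates[, 1], rates[, 4])
  expect_gt(r_sc, 0)
  expect_gt(r_sco, 0)
  expect_gt(r_sc, r_priv)
})
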