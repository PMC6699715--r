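test_that("a fully random policy has loglik n * log(0.5)", {
  pars <- social_rl_params(beta_p = 0, alpha_p = 0.5, beta_s = 0,
                           alpha_s = 0.5, kappa = 0, alpha_o = 0.3)
  tr <- toy_session(4, pars)
  expect_equal(as.numeric(session_loglik(pars, tr, "social")),
               nrow(tr) * log(0.5))
})

test_that("session_loglik equals the log-probabilities recorded during
          simulation, bit-exactly", {
  for (seed in c(2, 19, 57)) {
    pars <- mid_params()
    tr <- toy_session(seed, pars)
    expect_identical(as.numeric(session_loglik(pars, tr, "social")),
                     sum(tr$logp_choice))
  }
})

test_that("log posterior decomposes into likelihood plus analytic priors", {
  pars <- mid_params()
  tr <- toy_session(6, pars)
  pri <- prior_spec()
  analytic <- sum(dgamma(c(pars[["beta_p"]], pars[["beta_s"]]), shape = 1.2,
                         scale = 5, log = TRUE)) +
    sum(dbeta(c(pars[["alpha_p"]], pars[["alpha_s"]], pars[["kappa"]],
                pars[["alpha_o"]]), 1.1, 1.1, log = TRUE))
  expect_equal(log_prior(pars, "social", pri), analytic)
  expect_equal(log_posterior(pars, tr, "social", pri),
               as.numeric(session_loglik(pars, tr, "social")) + analytic)
  # empty data: LPP is the prior alone
  expect_equal(log_posterior(pars, tr[0, ], "social", pri), analytic)
  # at the optimum the decomposition holds to machine precision
  fit <- withr::with_seed(1, fit_subject(tr, "social"))
  expect_equal(fit$lpp - fit$loglik, log_prior(fit$params, "social", pri),
               tolerance = 1e-12)
})

test_that("the optimizer matches an exhaustive grid on the 2-parameter
          model", {
  pars <- social_rl_params(3, 0.4, 3, 0.4, 0, 0)
  cfg <- task_config()
  tr <- toy_session(13, pars, cfg)
  priv <- tr[tr$condition == "private", ]
  grid_alpha <- seq(0.012, 0.988, length.out = 41)
  grid_beta <- seq(0.05, 20, length.out = 41)
  grid_lpp <- outer(grid_alpha, grid_beta, Vectorize(function(a, b) {
    log_posterior(c(alpha = a, beta = b), priv, "qlearn")
  }))
  fit <- withr::with_seed(2, fit_subject(priv, "qlearn"))
  expect_gte(fit$lpp, max(grid_lpp) - 1e-6)
})

test_that("fitting is deterministic given the RNG state", {
  tr <- toy_session(8)
  f1 <- withr::with_seed(3, fit_subject(tr, "social"))
  f2 <- withr::with_seed(3, fit_subject(tr, "social"))
  expect_identical(f1, f2)
})

test_that("many learning blocks recover the generating parameters", {
  # identification of the social parameters comes from the early, still
  # uncertain trials of each block, so information accrues with the number
  # of blocks rather than with block length
  truth <- mid_params()
  tr <- withr::with_seed(99, {
    do.call(rbind, lapply(1:25, function(k) {
      s <- simulate_session(truth)
      s$block_id <- s$block_id + (k - 1) * 6L
      s
    }))
  })
  fit <- withr::with_seed(4, fit_subject(tr, "social"))
  est <- fit$params
  for (p in c("alpha_p", "alpha_s", "kappa", "alpha_o"))
    expect_lt(abs(est[[p]] - truth[[p]]), 0.1)
  for (p in c("beta_p", "beta_s"))
    expect_lt(abs(est[[p]] - truth[[p]]) / truth[[p]], 0.25)
})

test_that("BMS respects symmetry, permutation and overwhelming evidence", {
  lme_eq <- matrix(c(-10, -10, -12, -12), 2, 2,
                   dimnames = list(NULL, c("a", "b")))
  r <- bms(t(lme_eq) * 0 - 10)  # identical columns, 2 subjects
  expect_equal(unname(r$posterior_prob), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sum(r$posterior_prob), 1)
  expect_equal(sum(r$exceedance_prob), 1)
  expect_equal(unname(r$exceedance_prob), c(0.5, 0.5), tolerance = 0.02)

  # antisymmetric 2x2 case
  r2 <- bms(matrix(c(0, -1, -1, 0), 2, 2))
  expect_equal(unname(r2$posterior_prob), c(0.5, 0.5), tolerance = 1e-6)

  # one model better by 10 log-units for all 50 subjects
  lme <- cbind(best = rep(0, 50), worst = rep(-10, 50))
  r3 <- bms(lme)
  expect_gt(r3$posterior_prob[["best"]], 0.95)
  expect_gt(r3$exceedance_prob[["best"]], 0.999)

  # permuting model order permutes the outputs
  r4 <- bms(lme[, c("worst", "best")])
  expect_equal(unname(r4$posterior_prob[c("best", "worst")]),
               unname(r3$posterior_prob[c("best", "worst")]),
               tolerance = 1e-8)

  expect_error(bms(cbind(c(0, -Inf), c(-1, 0))), "finite")
  expect_error(bms(matrix(0, 1, 2)), ">= 2")
})

test_that("predictive simulations correlate with observed performance", {
  cohort <- withr::with_seed(31, {
    ids <- sprintf("P%02d", 1:12)
    do.call(rbind, lapply(ids, function(id) {
      pars <- social_rl_params(runif(1, 0.5, 6), runif(1, 0.1, 0.9),
                               runif(1, 0.5, 6), runif(1, 0.1, 0.9),
                               runif(1, 0, 0.4), runif(1, 0.1, 0.8))
      simulate_session(pars, subject_id = id)
    }))
  })
  fits <- withr::with_seed(5, fit_cohort(cohort, "social", n_restarts = 5))
  pc <- withr::with_seed(6, predictive_check(fits, cohort, reps = 20))
  expect_true(all(pc$correlations > 0.2))
  expect_error(predictive_check(fits, cohort, reps = 0), ">= 1")
})
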