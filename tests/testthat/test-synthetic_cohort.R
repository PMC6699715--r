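test_that("score margins and copula correlation match the specification", {
  spec <- cohort_spec(n_subjects = 10000, n_samples = 1)
  co <- generate_cohort(spec, seed = 404, simulate = FALSE)
  s <- co$subjects
  se3 <- 3 * spec$depression_sd / sqrt(10000)
  expect_lt(abs(mean(s$depression) - spec$depression_mean), se3)
  expect_lt(abs(sd(s$depression) - spec$depression_sd), 3 * 0.05)
  expect_lt(abs(mean(s$anxiety) - spec$anxiety_mean),
            3 * spec$anxiety_sd / sqrt(10000))
  expect_true(all(s$depression >= 0 & s$depression <= 21))
  expect_true(all(s$depression == round(s$depression)))
  # right skew
  expect_gt(mean(s$depression) , stats::median(s$depression))
  expect_lt(abs(cor(s$depression, s$anxiety) - spec$score_correlation), 0.05)
})

test_that("the depression coupling onto alpha_s is calibrated", {
  co <- generate_cohort(cohort_spec(n_subjects = 10000, n_samples = 1),
                        seed = 405, simulate = FALSE)
  expect_lt(abs(cor(co$subjects$depression, co$subjects$alpha_s) + 0.25),
            0.05)
  # null coupling: independence of all parameters from depression
  co0 <- generate_cohort(cohort_spec(n_subjects = 10000, n_samples = 1,
                                     coupling_r = 0),
                         seed = 406, simulate = FALSE)
  for (p in param_names())
    expect_lt(abs(cor(co0$subjects$depression, co0$subjects[[p]])), 0.05)
})

test_that("parameter population moments are honoured", {
  co <- generate_cohort(cohort_spec(n_subjects = 10000, n_samples = 1),
                        seed = 407, simulate = FALSE)
  pop <- default_param_population()
  for (i in seq_len(nrow(pop))) {
    x <- co$subjects[[pop$param[i]]]
    expect_lt(abs(mean(x) - pop$mean[i]), 0.08 * max(1, pop$mean[i]))
    expect_lt(abs(sd(x) - pop$sd[i]), 0.1 * max(1, pop$sd[i]))
    if (pop$type[i] == "rate") expect_true(all(x >= 0 & x <= 1))
  }
})

test_that("cohorts are reproducible and structurally complete", {
  spec <- cohort_spec(n_subjects = 4, n_samples = 2)
  c1 <- generate_cohort(spec, seed = 11)
  c2 <- generate_cohort(spec, seed = 11)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$sessions, c2$sessions)
  expect_equal(nrow(c1$subjects), 8L)
  expect_equal(sort(unique(c1$sessions$subject_id)),
               sort(c1$subjects$subject_id))
  # one full session per subject
  expect_equal(as.integer(table(c1$sessions$subject_id)), rep(120L, 8))
  # trust covariate present only on request
  expect_false("trust" %in% names(c1$subjects))
  c3 <- generate_cohort(cohort_spec(n_subjects = 30, n_samples = 1,
                                    trust = TRUE), seed = 12,
                        simulate = FALSE)
  expect_true(all(c3$subjects$trust %in% 1:9))
})

test_that("the symptom threshold splits scores at 8", {
  expect_equal(as.character(score_threshold(c(0, 7, 8, 21))),
               c("absent", "absent", "present", "present"))
  expect_error(score_threshold(22), "0-21")
  expect_error(score_threshold(-1), "0-21")
  expect_error(score_threshold(3.5), "0-21")
})
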