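test_that("pearson_correlation reproduces textbook cases and calibrates
          under the null", {
  r1 <- pearson_correlation(1:10, 1:10)
  expect_equal(r1$r, 1)
  expect_equal(r1$df, 8)
  r2 <- pearson_correlation(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r2$r, 1)
  expect_equal(r2$df, 1)
  expect_error(pearson_correlation(1:2, 1:2), ">= 3")
  expect_error(pearson_correlation(rep(1, 5), 1:5), "variance")

  # null calibration: rejection rate ~ alpha
  rej <- withr::with_seed(9, vapply(1:2000, function(i)
    pearson_correlation(rnorm(50), rnorm(50))$p_value < 0.05, logical(1)))
  expect_equal(mean(rej), 0.05, tolerance = 0.3)
})

test_that("meta_correlation pools with Fisher-z random effects", {
  mk <- function(r, n) list(r = r, n = n)
  m <- meta_correlation(list(mk(-0.30, 50), mk(-0.36, 50)))
  expect_equal(m$effect, -0.33, tolerance = 0.02)
  expect_lt(m$p_value, 0.001)
  expect_lt(m$z_stat, -3)

  ident <- meta_correlation(list(mk(0.4, 60), mk(0.4, 60)))
  expect_equal(ident$effect, 0.4, tolerance = 1e-6)
  expect_equal(ident$tau2, 0)

  sym <- meta_correlation(list(mk(0.5, 50), mk(-0.5, 50)))
  expect_equal(sym$effect, 0, tolerance = 1e-8)

  triple <- meta_correlation(list(mk(0.3, 50), mk(0.3, 50), mk(0.3, 50)))
  expect_equal(triple$effect, 0.3, tolerance = 1e-6)
  expect_lt(diff(triple$ci95), diff(meta_correlation(
    list(mk(0.3, 50), mk(0.3, 50)))$ci95) + 1e-9)

  expect_error(meta_correlation(list(mk(0.3, 50))), ">= 2")
  expect_error(meta_correlation(list(mk(0.3, 50), mk(0.3, 3))), "n > 3")
})

test_that("meta_mean pools sample means by precision", {
  m <- meta_mean(c(0.65, 0.65), c(0.015, 0.015))
  expect_equal(m$effect, 0.65)
  m2 <- meta_mean(c(0.6, 0.7), c(0.01, 0.03))
  expect_gt(m2$effect, 0.6)
  expect_lt(m2$effect, 0.65)  # precision-weighted toward the tighter sample
})

test_that("the threshold classifier separates, fails and compares as
          expected", {
  # perfect separation
  lab <- rep(c(FALSE, TRUE), each = 25)
  feat <- ifelse(lab, 2, 0)
  rep1 <- withr::with_seed(41, threshold_classifier_cv(feat, lab,
                                                       n_repeats = 20))
  expect_true(all(rep1$per_repeat$accuracy == 1))
  expect_true(all(rep1$per_repeat$sensitivity == 1))
  expect_true(all(rep1$per_repeat$specificity == 1))

  # near-separable: label + small noise
  feat2 <- withr::with_seed(42, as.numeric(lab) + rnorm(50, sd = 0.1))
  rep2 <- withr::with_seed(43, threshold_classifier_cv(feat2, lab,
                                                       n_repeats = 50))
  expect_gt(mean(rep2$per_repeat$accuracy), 0.9)

  # uninformative feature: held-out accuracy near chance
  feat3 <- withr::with_seed(44, rnorm(100))
  lab3 <- rep(c(FALSE, TRUE), 50)
  rep3 <- withr::with_seed(45, threshold_classifier_cv(feat3, lab3,
                                                       n_repeats = 50))
  expect_equal(mean(rep3$per_repeat$accuracy), 0.5, tolerance = 0.1)

  # direction is learned: inverted feature classifies equally well
  rep4 <- withr::with_seed(43, threshold_classifier_cv(-feat2, lab,
                                                       n_repeats = 50))
  expect_equal(mean(rep4$per_repeat$accuracy),
               mean(rep2$per_repeat$accuracy), tolerance = 0.05)

  cmp0 <- compare_classifiers(rep2, rep2, "accuracy")
  expect_equal(cmp0$t_stat, 0)
  expect_equal(cmp0$df, 98)
  cmp <- compare_classifiers(rep2, rep3, "accuracy")
  expect_error(compare_classifiers(rep1, rep2, "accuracy"), "differ")
  expect_gt(cmp$t_stat, 5)

  expect_error(threshold_classifier_cv(feat[1:10], lab[1:10]), ">= 20")
  expect_error(threshold_classifier_cv(feat, rep(TRUE, 50)), "both classes")
})

test_that("classifier comparison has the closed-form t for shifted samples", {
  a <- withr::with_seed(46, rnorm(100, mean = 0.7, sd = 0.05))
  b <- a - 0.02
  ra <- list(per_repeat = data.frame(accuracy = a), n_repeats = 100L)
  rb <- list(per_repeat = data.frame(accuracy = b), n_repeats = 100L)
  cmp <- compare_classifiers(ra, rb, "accuracy")
  expect_equal(cmp$df, 198)
  expect_equal(cmp$t_stat, 0.02 / (sd(a) * sqrt(2 / 100)), tolerance = 0.02)
})

test_that("long-format export carries scores onto every trial", {
  co <- generate_cohort(cohort_spec(n_subjects = 3, n_samples = 1),
                        seed = 50)
  tab <- export_long_table(co)
  expect_equal(nrow(tab), nrow(co$sessions))
  expect_true(all(c("depression", "anxiety", "condition", "correct")
                  %in% names(tab)))
  one <- tab[tab$subject_id == co$subjects$subject_id[1], ]
  expect_equal(unique(one$depression), co$subjects$depression[1])
})
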