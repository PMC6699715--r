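# ---- per-subject summaries --------------------------------------------------

#' Per-subject correct-choice rates by condition
#'
#' @param trials Trial-log data frame (must contain `subject_id`,
#'   `condition`, `correct`).
#' @return Wide data frame: `subject_id` plus one column per condition with
#'   the subject's mean correct-choice rate.
#' @export
correct_rates <- function(trials) {
  agg <- aggregate(correct ~ subject_id + condition, data = trials,
                   FUN = mean)
  out <- data.frame(subject_id = unique(trials$subject_id),
                    stringsAsFactors = FALSE)
  for (cn in conditions()) {
    sub <- agg[agg$condition == cn, , drop = FALSE]
    out[[cn]] <- sub$correct[match(out$subject_id, sub$subject_id)]
  }
  out
}

#' Export a tidy long-format trial table
#'
#' One row per trial with questionnaire scores attached, suitable for
#' external mixed-effects logistic regression or SEM software.
#'
#' @param cohort A [generate_cohort()] cohort.
#' @param file Optional CSV path; if given the table is also written there.
#' @return The long-format data frame (invisibly if `file` is given).
#' @export
export_long_table <- function(cohort, file = NULL) {
  subj <- cohort$subjects
  tab <- merge(cohort$sessions,
               subj[, c("subject_id", "sample_id", "depression", "anxiety")],
               by = "subject_id", sort = FALSE)
  tab <- tab[order(tab$subject_id, tab$block_id, tab$trial), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(file)) {
    write.csv(tab, file, row.names = FALSE, na = "")
    return(invisible(tab))
  }
  tab
}

# ---- correlation ------------------------------------------------------------

#' Pearson correlation with t-test
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite, non-constant).
#' @return A list of class `"correlation_result"` with `r`, `t_stat`, `df`,
#'   `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 paired observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite", call. = FALSE)
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance input", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), t_stat = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

# ---- meta-analysis ----------------------------------------------------------

#' Random-effects meta-analysis of correlations
#'
#' Fisher-z transforms each sample's correlation (variance 1/(n-3)), pools
#' them with a random-effects model (DerSimonian-Laird by default, via
#' \pkg{metafor}) and back-transforms the pooled effect.
#'
#' @param per_sample List of [pearson_correlation()] results (or lists with
#'   elements `r` and `n`), one per sample; >= 2 samples, each n >= 4.
#' @param method Heterogeneity estimator passed to [metafor::rma()]
#'   (default `"DL"`; `"REML"` available).
#' @return A list of class `"meta_result"` with `effect` (pooled r), `ci95`,
#'   `z_stat`, `p_value`, `tau2`, `k`.
#' @export
meta_correlation <- function(per_sample, method = "DL") {
  if (length(per_sample) < 2L) stop("need >= 2 samples", call. = FALSE)
  r <- vapply(per_sample, function(s) s$r, numeric(1))
  n <- vapply(per_sample, function(s) s$n, numeric(1))
  if (any(n <= 3)) stop("each sample needs n > 3", call. = FALSE)
  fit <- metafor::rma(yi = atanh(r), vi = 1 / (n - 3), method = method)
  structure(list(effect = tanh(as.numeric(fit$b)),
                 ci95 = tanh(c(fit$ci.lb, fit$ci.ub)),
                 z_stat = as.numeric(fit$zval),
                 p_value = as.numeric(fit$pval),
                 tau2 = fit$tau2, k = length(r)),
            class = "meta_result")
}

#' Random-effects meta-analysis of sample means
#'
#' Pools per-sample means weighted by 1/SEM^2 with the same random-effects
#' machinery as [meta_correlation()].
#'
#' @param means,sems Numeric vectors of per-sample means and standard errors.
#' @inheritParams meta_correlation
#' @return A `"meta_result"` list (effect on the mean scale).
#' @export
meta_mean <- function(means, sems, method = "DL") {
  if (length(means) < 2L || length(means) != length(sems))
    stop("need >= 2 samples with matching sems", call. = FALSE)
  fit <- metafor::rma(yi = means, sei = sems, method = method)
  structure(list(effect = as.numeric(fit$b),
                 ci95 = c(fit$ci.lb, fit$ci.ub),
                 z_stat = as.numeric(fit$zval),
                 p_value = as.numeric(fit$pval),
                 tau2 = fit$tau2, k = length(means)),
            class = "meta_result")
}

# ---- threshold classifier ---------------------------------------------------

eval_cutoff <- function(feature, present, cutoff, direction) {
  pred <- if (direction == "ge") feature >= cutoff else feature <= cutoff
  sens <- mean(pred[present])
  spec <- mean(!pred[!present])
  c(accuracy = mean(pred == present), sensitivity = sens, specificity = spec)
}

train_cutoff <- function(feature, present) {
  v <- sort(unique(feature))
  cand <- if (length(v) > 1L) (v[-1] + v[-length(v)]) / 2 else v
  best <- list(j = -Inf)
  for (dir in c("ge", "le")) {
    js <- vapply(cand, function(ct) {
      m <- eval_cutoff(feature, present, ct, dir)
      m[["sensitivity"]] + m[["specificity"]]
    }, numeric(1))
    jmax <- max(js)
    if (jmax > best$j + 1e-12) {
      hits <- which(js >= jmax - 1e-12)
      # ties broken toward the middle of the tied cutoff midpoints
      pick <- hits[ceiling(length(hits) / 2)]
      best <- list(j = jmax, cutoff = cand[pick], direction = dir)
    }
  }
  best
}

#' Out-of-sample threshold classifier
#'
#' Repeated random half-split classification of a binary symptom label from
#' a single scalar feature. On each training half the cut-off (and its
#' direction) maximizing sensitivity + specificity (Youden's J) is chosen
#' over the midpoints of adjacent sorted feature values; accuracy,
#' sensitivity and specificity are then measured on the held-out half.
#' Splits leaving a single class in either half are resampled (and counted).
#' Uses the current RNG state.
#'
#' @param feature Per-subject scalar feature.
#' @param labels Logical vector (`TRUE` = symptoms present) or a factor from
#'   [score_threshold()].
#' @param n_repeats Number of random splits (default 100).
#' @param train_fraction Fraction of subjects in the training half.
#' @return A list of class `"classifier_report"`: `summary` (mean and sem of
#'   each rate), `per_repeat` (per-split rates and cut-offs), `n_repeats`,
#'   `n_resampled`.
#' @export
threshold_classifier_cv <- function(feature, labels, n_repeats = 100L,
                                    train_fraction = 0.5) {
  present <- if (is.logical(labels)) labels else labels == "present"
  n <- length(feature)
  if (n < 20L) stop("need >= 20 subjects", call. = FALSE)
  if (length(present) != n) stop("feature/labels length mismatch",
                                 call. = FALSE)
  if (all(present) || !any(present))
    stop("both classes must be present", call. = FALSE)
  n_train <- max(1L, min(n - 1L, round(n * train_fraction)))
  rows <- vector("list", n_repeats)
  n_resampled <- 0L
  for (rep_i in seq_len(n_repeats)) {
    repeat {
      idx <- sample.int(n, n_train)
      tr <- present[idx]
      te <- present[-idx]
      if (any(tr) && !all(tr) && any(te) && !all(te)) break
      n_resampled <- n_resampled + 1L
    }
    cut <- train_cutoff(feature[idx], present[idx])
    m <- eval_cutoff(feature[-idx], present[-idx], cut$cutoff, cut$direction)
    rows[[rep_i]] <- data.frame(accuracy = m[["accuracy"]],
                                sensitivity = m[["sensitivity"]],
                                specificity = m[["specificity"]],
                                cutoff = cut$cutoff,
                                direction = cut$direction,
                                stringsAsFactors = FALSE)
  }
  per_repeat <- do.call(rbind, rows)
  sem <- function(x) sd(x) / sqrt(length(x))
  metrics <- c("accuracy", "sensitivity", "specificity")
  summary <- data.frame(metric = metrics,
                        mean = vapply(per_repeat[metrics], mean, numeric(1)),
                        sem = vapply(per_repeat[metrics], sem, numeric(1)),
                        row.names = NULL)
  structure(list(summary = summary, per_repeat = per_repeat,
                 n_repeats = as.integer(n_repeats),
                 n_resampled = n_resampled),
            class = "classifier_report")
}

#' Compare two classifier reports on a metric
#'
#' Two-sample pooled-variance t-test across repeats (df = 2 * n_repeats - 2).
#'
#' @param report_a,report_b [threshold_classifier_cv()] reports with equal
#'   `n_repeats`.
#' @param metric `"accuracy"`, `"sensitivity"` or `"specificity"`.
#' @return List with `t_stat`, `df`, `p_value` (positive t means `report_a`
#'   scores higher).
#' @export
compare_classifiers <- function(report_a, report_b,
                                metric = c("accuracy", "sensitivity",
                                           "specificity")) {
  metric <- match.arg(metric)
  if (report_a$n_repeats != report_b$n_repeats)
    stop("repeat counts differ", call. = FALSE)
  a <- report_a$per_repeat[[metric]]
  b <- report_b$per_repeat[[metric]]
  if (sd(a) == 0 && sd(b) == 0) {
    return(list(t_stat = 0, df = 2 * report_a$n_repeats - 2, p_value = 1))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
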