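# ---- design -----------------------------------------------------------------

#' Parameter-recovery design
#'
#' Describes one recovery experiment: for each of the six model parameters,
#' `n_datasets` cohorts of `n_subjects` are simulated in which that
#' parameter follows a covariate (by default a deterministic monotone linear
#' map of depression-like scores onto the parameter's fitted range,
#' generative r = 1) while the other parameters are drawn uniformly within
#' their fitted ranges. Sessions are refit by MAP and every recovered
#' parameter is correlated with the covariate.
#'
#' @param n_datasets Datasets per manipulated parameter (default 100).
#' @param n_subjects Subjects per dataset (default 100).
#' @param coupling_strength Correlation strength of the covariate-parameter
#'   map in \[0, 1\]; 1 (default) is the deterministic linear map, 0 makes
#'   the parameter independent of the covariate (null calibration).
#' @param alpha_level Two-sided significance threshold (default 0.05).
#' @param param_ranges Data frame `param, lo, hi`
#'   (default [param_population_ranges()], the central 95% band of the
#'   generative population).
#' @param config [task_config()] for the simulated sessions.
#' @param n_restarts Optimizer restarts per fit.
#' @return A list of class `"recovery_design"`.
#' @export
recovery_design <- function(n_datasets = 100L, n_subjects = 100L,
                            coupling_strength = 1, alpha_level = 0.05,
                            param_ranges = param_population_ranges(),
                            config = task_config(), n_restarts = 10L) {
  stopifnot(n_datasets >= 1L, n_subjects >= 3L,
            coupling_strength >= 0, coupling_strength <= 1,
            alpha_level > 0, alpha_level < 1)
  structure(list(n_datasets = as.integer(n_datasets),
                 n_subjects = as.integer(n_subjects),
                 coupling_strength = coupling_strength,
                 alpha_level = alpha_level,
                 param_ranges = param_ranges, config = config,
                 n_restarts = as.integer(n_restarts)),
            class = "recovery_design")
}

# covariate: integer scores from the default depression margin (redrawn
# until non-constant)
draw_covariate <- function(n) {
  margin <- score_margin(5.2, 4.5)
  repeat {
    x <- margin$qfun(runif(n))
    if (length(unique(x)) > 1L) return(x)
  }
}

# map the covariate onto [lo, hi]: with strength 1 a deterministic linear
# map; lower strengths mix in independent normal noise before mapping
couple_to_range <- function(x, lo, hi, strength) {
  y <- if (strength >= 1) {
    x
  } else {
    strength * as.numeric(scale(x)) +
      sqrt(1 - strength^2) * rnorm(length(x))
  }
  if (max(y) == min(y)) y <- y + rnorm(length(y), sd = 1e-8)
  lo + (y - min(y)) / (max(y) - min(y)) * (hi - lo)
}

#' Parameter recovery analysis
#'
#' Runs the full recovery design and reports, for every (manipulated,
#' recovered) parameter pair, the fraction of datasets in which the
#' recovered parameter correlates significantly with the covariate, and the
#' mean recovered correlation. Diagonal entries measure sensitivity;
#' off-diagonal entries are false alarms. Uses the current RNG state.
#'
#' @param design A [recovery_design()].
#' @param priors [prior_spec()] for the refits.
#' @param params Which parameters to manipulate (default: all six).
#' @param progress If `TRUE`, print one line per manipulated parameter.
#' @return A list of class `"recovery_matrix"` with `detection_rate` and
#'   `mean_r` (manipulated x recovered matrices, one row per manipulated
#'   parameter, six columns) and the `design`.
#' @export
parameter_recovery <- function(design = recovery_design(),
                               priors = prior_spec(),
                               params = param_names(), progress = FALSE) {
  pn <- param_names()
  stopifnot(all(params %in% pn))
  ranges <- design$param_ranges
  if (!all(pn %in% ranges$param))
    stop("param_ranges must cover all six parameters", call. = FALSE)
  ranges <- ranges[match(pn, ranges$param), , drop = FALSE]
  detect <- matrix(0, length(params), 6,
                   dimnames = list(manipulated = params, recovered = pn))
  mean_r <- detect
  for (row in seq_along(params)) {
    p <- match(params[row], pn)
    sig <- matrix(NA, design$n_datasets, 6)
    rr <- sig
    for (d in seq_len(design$n_datasets)) {
      n <- design$n_subjects
      x <- draw_covariate(n)
      true <- matrix(runif(n * 6, min = rep(ranges$lo, each = n),
                           max = rep(ranges$hi, each = n)), n, 6,
                     dimnames = list(NULL, pn))
      true[, p] <- couple_to_range(x, ranges$lo[p], ranges$hi[p],
                                   design$coupling_strength)
      rec <- matrix(NA_real_, n, 6, dimnames = list(NULL, pn))
      for (j in seq_len(n)) {
        trials <- simulate_session(true[j, ], design$config)
        fit <- fit_subject(trials, "social", priors = priors,
                           n_restarts = design$n_restarts)
        rec[j, ] <- fit$params[pn]
      }
      for (q in seq_along(pn)) {
        ct <- pearson_correlation(x, rec[, q])
        sig[d, q] <- ct$p_value < design$alpha_level
        rr[d, q] <- ct$r
      }
    }
    detect[row, ] <- colMeans(sig)
    mean_r[row, ] <- colMeans(rr)
    if (progress)
      message(sprintf("recovery %s: detection %.2f, mean r %.2f",
                      pn[p], detect[row, p], mean_r[row, p]))
  }
  structure(list(detection_rate = detect, mean_r = mean_r, design = design),
            class = "recovery_matrix")
}

#' Pooled off-diagonal false-alarm rate
#'
#' Fraction of significant (dataset, non-manipulated parameter) correlation
#' tests pooled across all off-diagonal pairs, optionally excluding the
#' (alpha_p, beta_p) trade-off pair. At small dataset counts the per-pair
#' rates are coarsely quantized; the pooled rate remains a stable estimate
#' of specificity.
#'
#' @param recovery A [parameter_recovery()] result.
#' @param exclude_private_pair Exclude the (alpha_p, beta_p) pair.
#' @return The pooled false-alarm fraction.
#' @export
false_alarm_rate <- function(recovery, exclude_private_pair = TRUE) {
  d <- recovery$detection_rate
  mask <- matrix(TRUE, nrow(d), ncol(d), dimnames = dimnames(d))
  for (rn in rownames(d)) mask[rn, rn] <- FALSE
  if (exclude_private_pair) {
    if ("alpha_p" %in% rownames(d)) mask["alpha_p", "beta_p"] <- FALSE
    if ("beta_p" %in% rownames(d)) mask["beta_p", "alpha_p"] <- FALSE
  }
  mean(d[mask])
}

#' Maximal off-diagonal false-alarm rate
#'
#' @param recovery A [parameter_recovery()] result.
#' @param exclude_private_pair Exclude the (alpha_p, beta_p) pair, whose
#'   trade-off is a known identifiability limit of softmax Q-learning.
#' @return The largest off-diagonal detection rate considered.
#' @export
max_false_alarm <- function(recovery, exclude_private_pair = TRUE) {
  d <- recovery$detection_rate
  mask <- matrix(TRUE, nrow(d), ncol(d), dimnames = dimnames(d))
  for (rn in rownames(d)) mask[rn, rn] <- FALSE
  if (exclude_private_pair) {
    if ("alpha_p" %in% rownames(d)) mask["alpha_p", "beta_p"] <- FALSE
    if ("beta_p" %in% rownames(d)) mask["beta_p", "alpha_p"] <- FALSE
  }
  max(d[mask])
}

# ---- model recovery ---------------------------------------------------------

# a virtual demonstrator replayed as if it were a subject: a plain
# Q-learner whose trial log carries the social columns filled by an
# independent partner stream
demonstrator_session <- function(config, dem_params, subject_id) {
  schedule <- build_schedule(config)
  partner <- simulate_demonstrator(schedule, dem_params)
  simulate_participant(schedule, partner,
                       qlearn_as_social(dem_params[["alpha"]],
                                        dem_params[["beta"]]),
                       subject_id = subject_id)
}

#' Model recovery on simulated demonstrators
#'
#' Simulates `n_demonstrators` plain Q-learners on full schedules, fits both
#' the plain Q-learning model and the 6-parameter social RL model by MAP,
#' and runs random-effects model selection on the per-subject LPPs. Data
#' generated without social influence should be won by the simpler model.
#' Uses the current RNG state.
#'
#' @param n_demonstrators Number of simulated demonstrators (>= 2).
#' @param dem_params [demonstrator_params()] generating the data.
#' @param config [task_config()].
#' @param priors [prior_spec()].
#' @param n_restarts Optimizer restarts per fit.
#' @return A list of class `"model_recovery"` with `bms` (the
#'   [bms()] result), `evidence` (subjects x models LPP matrix) and
#'   `fits` (per-model lists of fit results).
#' @export
model_recovery <- function(n_demonstrators = 100L,
                           dem_params = demonstrator_params(),
                           config = task_config(), priors = prior_spec(),
                           n_restarts = 10L) {
  if (n_demonstrators < 2L) stop("need >= 2 demonstrators", call. = FALSE)
  ids <- sprintf("D%03d", seq_len(n_demonstrators))
  fits_q <- vector("list", n_demonstrators)
  fits_s <- vector("list", n_demonstrators)
  for (i in seq_len(n_demonstrators)) {
    trials <- demonstrator_session(config, dem_params, ids[i])
    fits_q[[i]] <- fit_subject(trials, "qlearn", priors = priors,
                               n_restarts = n_restarts)
    fits_s[[i]] <- fit_subject(trials, "social", priors = priors,
                               n_restarts = n_restarts)
  }
  names(fits_q) <- names(fits_s) <- ids
  evidence <- cbind(social = vapply(fits_s, `[[`, numeric(1), "lpp"),
                    qlearn = vapply(fits_q, `[[`, numeric(1), "lpp"))
  structure(list(bms = bms(evidence), evidence = evidence,
                 fits = list(social = fits_s, qlearn = fits_q)),
            class = "model_recovery")
}

# ---- simulation from fitted parameters --------------------------------------

#' Simulate behavior from fitted parameters
#'
#' For each subject, simulates `reps` fresh sessions (new schedule and new
#' demonstrator per repetition, so simulated data are independent of the
#' experienced contingencies) from the fitted parameters and averages the
#' correct-choice rate per condition. The output mirrors [correct_rates()]
#' so identical statistics can be run on observed and simulated data. Uses
#' the current RNG state.
#'
#' @param fits Named list of social-model `fit_result`s.
#' @param reps Repetitions per subject (default 100).
#' @param config [task_config()].
#' @return Wide data frame: `subject_id` plus one mean simulated correct
#'   rate column per condition.
#' @export
simulate_from_fits <- function(fits, reps = 100L, config = task_config()) {
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  out <- lapply(names(fits), function(id) {
    pars <- fits[[id]]$params
    acc <- NULL
    for (r in seq_len(reps)) {
      cr <- correct_rates(simulate_session(pars, config, subject_id = id))
      acc <- if (is.null(acc)) cr[, -1] else acc + cr[, -1]
    }
    cbind(subject_id = id, acc / reps, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
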