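# ---- population of model parameters -----------------------------------------

#' Default parameter population
#'
#' Population means and SDs of the six model parameters used by the cohort
#' generator, matching values typical of participants fitted on this task
#' (temperatures around 2, learning rates around 0.6, a small imitation rate
#' and a moderate observational rate). Temperatures are drawn log-normal,
#' rates logit-normal, moment-matched to these values.
#'
#' @return Data frame with columns `param`, `mean`, `sd`, `type`.
#' @export
default_param_population <- function() {
  data.frame(
    param = param_names(),
    mean = c(2.20, 0.58, 1.83, 0.60, 0.13, 0.46),
    sd = c(2.40, 0.26, 1.73, 0.31, 0.10, 0.31),
    type = c("temp", "rate", "temp", "rate", "rate", "rate"),
    stringsAsFactors = FALSE)
}

# log-normal / logit-normal location and scale for one population row;
# the logit-normal has no closed-form moments, so (mu, sigma) are solved
# numerically so that the realized mean and SD match the stated ones
pop_location <- function(mean, sd, type) {
  if (type == "temp") {
    sdlog2 <- log(1 + (sd / mean)^2)
    return(list(mu = log(mean) - sdlog2 / 2, sigma = sqrt(sdlog2)))
  }
  z <- seq(-8, 8, length.out = 2001)
  w <- dnorm(z)
  w <- w / sum(w)
  moments <- function(mu, sigma) {
    p <- plogis(mu + sigma * z)
    m <- sum(w * p)
    c(m, sqrt(sum(w * (p - m)^2)))
  }
  obj <- function(par) {
    mo <- moments(par[1], exp(par[2]))
    (mo[1] - mean)^2 + (mo[2] - sd)^2
  }
  start <- c(qlogis(mean), log(sd / (mean * (1 - mean))))
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 1000, reltol = 1e-12))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Population quantiles of the model parameters
#'
#' Quantiles of the generative population distributions; the default
#' 2.5%/97.5% band serves as the "fitted range" used by the recovery
#' analyses.
#'
#' @param population A [default_param_population()]-shaped data frame.
#' @param probs Two quantile levels.
#' @return Data frame with columns `param`, `lo`, `hi`.
#' @export
param_population_ranges <- function(population = default_param_population(),
                                    probs = c(0.025, 0.975)) {
  out <- lapply(seq_len(nrow(population)), function(i) {
    loc <- pop_location(population$mean[i], population$sd[i],
                        population$type[i])
    q <- qnorm(probs, loc$mu, loc$sigma)
    if (population$type[i] == "temp") q <- exp(q) else q <- plogis(q)
    data.frame(param = population$param[i], lo = q[1], hi = q[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---- questionnaire score margins --------------------------------------------

# truncated negative binomial on 0..21, moment-matched to the target
# mean/SD after truncation (small deterministic solve over size and mu)
score_margin <- function(mean, sd) {
  if (sd^2 <= mean)
    stop("score margin needs sd^2 > mean (over-dispersion)", call. = FALSE)
  trunc_pmf <- function(size, mu) {
    pmf <- dnbinom(0:21, size = size, mu = mu)
    pmf / sum(pmf)
  }
  moments <- function(pmf) {
    m <- sum(0:21 * pmf)
    c(m, sqrt(sum((0:21 - m)^2 * pmf)))
  }
  obj <- function(lp) {
    mo <- moments(trunc_pmf(exp(lp[1]), exp(lp[2])))
    (mo[1] - mean)^2 + (mo[2] - sd)^2
  }
  start <- log(c(mean^2 / (sd^2 - mean), mean))
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-12))
  pmf <- trunc_pmf(exp(fit$par[1]), exp(fit$par[2]))
  cdf <- cumsum(pmf)
  list(pmf = pmf, cdf = cdf,
       qfun = function(u) findInterval(u, cdf, left.open = TRUE))
}

# grid "quadrature" over a standard normal
norm_grid <- function() {
  z <- seq(-8, 8, length.out = 8001)
  w <- dnorm(z)
  list(z = z, w = w / sum(w))
}

weighted_corr <- function(z, f, w) {
  mz <- sum(w * z); mf <- sum(w * f)
  cv <- sum(w * (z - mz) * (f - mf))
  vz <- sum(w * (z - mz)^2); vf <- sum(w * (f - mf)^2)
  cv / sqrt(vz * vf)
}

# attenuation of a latent-normal correlation through the logit link
logit_attenuation <- function(mu, sigma) {
  g <- norm_grid()
  weighted_corr(g$z, plogis(mu + sigma * g$z), g$w)
}

# correlation between a discretized score and its latent normal
score_latent_corr <- function(margin) {
  g <- norm_grid()
  weighted_corr(g$z, margin$qfun(pnorm(g$z)), g$w)
}

# ---- cohort specification ---------------------------------------------------

#' Synthetic cohort specification
#'
#' Describes a synthetic sample: right-skewed integer depression and anxiety
#' scores on the 0-21 questionnaire scale (truncated negative binomial
#' margins joined by a Gaussian copula), subject-level model parameters
#' drawn from the population distributions, a negative coupling between the
#' depression score and the social learning rate `alpha_s`, and one fully
#' simulated session per subject. Two independent samples (discovery /
#' replication) are generated by default.
#'
#' @param n_subjects Subjects per sample (default 50).
#' @param n_samples Number of independent samples (default 2).
#' @param depression_mean,depression_sd Target moments of the depression
#'   margin (defaults 5.2 and 4.5).
#' @param anxiety_mean,anxiety_sd Target moments of the anxiety margin
#'   (defaults 6.35 and 4.4).
#' @param score_correlation Gaussian-copula correlation between the two
#'   scores (default 0.6).
#' @param coupling_r Target Pearson correlation between depression score and
#'   `alpha_s` (default -0.25); the latent coupling is calibrated so the
#'   realized correlation matches this within +/- 0.05 at large n.
#' @param param_population Parameter population data frame
#'   ([default_param_population()]).
#' @param trust If `TRUE`, generate a 1-9 trustworthiness rating correlated
#'   (`trust_r`) with the imitation rate's latent value.
#' @param trust_r Latent correlation of the trust rating with `kappa`.
#' @param config [task_config()] used for the simulated sessions.
#' @param seed Optional integer seed used by [generate_cohort()].
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 50L, n_samples = 2L,
                        depression_mean = 5.2, depression_sd = 4.5,
                        anxiety_mean = 6.35, anxiety_sd = 4.4,
                        score_correlation = 0.6, coupling_r = -0.25,
                        param_population = default_param_population(),
                        trust = FALSE, trust_r = 0.3,
                        config = task_config(), seed = NULL) {
  stopifnot(n_subjects >= 1L, n_samples >= 1L,
            abs(score_correlation) < 1, abs(coupling_r) < 1,
            depression_sd > 0, anxiety_sd > 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_samples = as.integer(n_samples),
                 depression_mean = depression_mean,
                 depression_sd = depression_sd,
                 anxiety_mean = anxiety_mean, anxiety_sd = anxiety_sd,
                 score_correlation = score_correlation,
                 coupling_r = coupling_r,
                 param_population = param_population,
                 trust = trust, trust_r = trust_r,
                 config = config, seed = seed),
            class = "cohort_spec")
}

# latent coupling needed so the realized Pearson r(depression, alpha_s)
# matches the target, correcting for logit-link attenuation and score
# discretization
calibrate_coupling <- function(spec) {
  pop <- spec$param_population
  i <- which(pop$param == "alpha_s")
  loc <- pop_location(pop$mean[i], pop$sd[i], pop$type[i])
  a <- logit_attenuation(loc$mu, loc$sigma)
  margin <- score_margin(spec$depression_mean, spec$depression_sd)
  cc <- score_latent_corr(margin)
  r_latent <- spec$coupling_r / (a * cc)
  if (!is.finite(r_latent) || abs(r_latent) >= 1)
    stop("coupling calibration infeasible: target |r| = ",
         abs(spec$coupling_r), " exceeds what the population scale allows",
         call. = FALSE)
  r_latent
}

# ---- generation -------------------------------------------------------------

#' Generate a synthetic cohort
#'
#' Draws correlated depression/anxiety scores, subject-level model
#' parameters (with `alpha_s` coupled to the depression score's latent
#' normal), and simulates each subject's full session (schedule +
#' demonstrator + participant). With `seed` given in the spec (or as
#' argument), generation is fully reproducible and the caller's RNG state is
#' untouched.
#'
#' @param spec A [cohort_spec()].
#' @param seed Overrides `spec$seed` if given.
#' @param simulate If `FALSE`, skip session simulation (scores and
#'   parameters only; useful for large calibration checks).
#' @return A list of class `"cohort"` with `subjects` (one row per subject:
#'   ids, scores, optional trust rating, parameters) and `sessions` (the
#'   combined trial log; `NULL` when `simulate = FALSE`).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed,
                            simulate = TRUE) {
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            generate_cohort(spec, seed = NULL,
                                            simulate = simulate)))
  }
  dep_margin <- score_margin(spec$depression_mean, spec$depression_sd)
  anx_margin <- score_margin(spec$anxiety_mean, spec$anxiety_sd)
  r_latent <- calibrate_coupling(spec)
  pop <- spec$param_population
  rho <- spec$score_correlation
  subjects <- list()
  sessions <- list()
  for (s in seq_len(spec$n_samples)) {
    n <- spec$n_subjects
    z_dep <- rnorm(n)
    z_anx <- rho * z_dep + sqrt(1 - rho^2) * rnorm(n)
    dep <- dep_margin$qfun(pnorm(z_dep))
    anx <- anx_margin$qfun(pnorm(z_anx))
    pars <- matrix(NA_real_, n, nrow(pop),
                   dimnames = list(NULL, pop$param))
    z_kappa <- NULL
    for (i in seq_len(nrow(pop))) {
      loc <- pop_location(pop$mean[i], pop$sd[i], pop$type[i])
      z <- if (pop$param[i] == "alpha_s") {
        r_latent * z_dep + sqrt(1 - r_latent^2) * rnorm(n)
      } else {
        rnorm(n)
      }
      if (pop$param[i] == "kappa") z_kappa <- z
      x <- loc$mu + loc$sigma * z
      pars[, i] <- if (pop$type[i] == "temp") {
        pmin(exp(x), 100)
      } else {
        plogis(x)
      }
    }
    ids <- sprintf("S%d_%03d", s, seq_len(n))
    subj <- data.frame(subject_id = ids, sample_id = s,
                       depression = dep, anxiety = anx,
                       stringsAsFactors = FALSE)
    if (spec$trust) {
      zt <- spec$trust_r * z_kappa + sqrt(1 - spec$trust_r^2) * rnorm(n)
      subj$trust <- pmin(9L, pmax(1L, as.integer(round(5 + 2 * zt))))
    }
    subj <- cbind(subj, as.data.frame(pars))
    subjects[[s]] <- subj
    if (simulate) {
      sessions[[s]] <- do.call(rbind, lapply(seq_len(n), function(j) {
        simulate_session(pars[j, ], spec$config, subject_id = ids[j])
      }))
    }
  }
  structure(list(spec = spec,
                 subjects = do.call(rbind, subjects),
                 sessions = if (simulate) do.call(rbind, sessions) else NULL),
            class = "cohort")
}

#' Classify a depression score against the symptom threshold
#'
#' Symptoms are considered present for questionnaire scores of 8 or above.
#'
#' @param depression_score Integer score(s) in 0-21.
#' @return Factor with levels `"absent"`, `"present"`.
#' @export
score_threshold <- function(depression_score) {
  s <- depression_score
  if (any(!is.finite(s)) || any(s != round(s)) || any(s < 0) || any(s > 21))
    stop("scores must be integers in 0-21", call. = FALSE)
  factor(ifelse(s >= 8, "present", "absent"),
         levels = c("absent", "present"))
}
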