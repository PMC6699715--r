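# ---- priors -----------------------------------------------------------------

#' Prior specification for MAP fitting
#'
#' Temperatures carry a gamma prior (default shape 1.2, scale 5 on (0, Inf));
#' rate-type parameters (learning, imitation and observational rates) carry a
#' beta prior (default shape parameters 1.1, 1.1 on (0, 1)).
#'
#' @param temperature_shape,temperature_scale Gamma prior hyperparameters.
#' @param rate_shape1,rate_shape2 Beta prior hyperparameters.
#' @return A list of class `"prior_spec"`.
#' @export
prior_spec <- function(temperature_shape = 1.2, temperature_scale = 5,
                       rate_shape1 = 1.1, rate_shape2 = 1.1) {
  stopifnot(temperature_shape > 0, temperature_scale > 0,
            rate_shape1 > 0, rate_shape2 > 0)
  structure(list(temperature_shape = temperature_shape,
                 temperature_scale = temperature_scale,
                 rate_shape1 = rate_shape1, rate_shape2 = rate_shape2),
            class = "prior_spec")
}

model_par_info <- function(model) {
  switch(model,
         social = list(names = param_names(),
                       type = c("temp", "rate", "temp", "rate", "rate",
                                "rate")),
         qlearn = list(names = c("beta", "alpha"),
                       type = c("temp", "rate")),
         stop("unknown model: ", model, call. = FALSE))
}

#' Log prior density of a parameter vector
#'
#' @param params Named parameter vector (6 social RL parameters, or `beta`
#'   and `alpha` for the plain Q-learner).
#' @param model `"social"` or `"qlearn"`.
#' @param priors A [prior_spec()].
#' @return Sum of log prior densities; `-Inf` outside the support.
#' @export
log_prior <- function(params, model = c("social", "qlearn"),
                      priors = prior_spec()) {
  model <- match.arg(model)
  info <- model_par_info(model)
  th <- as.numeric(params[info$names])
  lp <- numeric(length(th))
  is_temp <- info$type == "temp"
  lp[is_temp] <- dgamma(th[is_temp], shape = priors$temperature_shape,
                        scale = priors$temperature_scale, log = TRUE)
  lp[!is_temp] <- dbeta(th[!is_temp], priors$rate_shape1, priors$rate_shape2,
                        log = TRUE)
  sum(lp)
}

# ---- likelihood -------------------------------------------------------------

# trial-log data frame -> argument list for the C++ likelihood kernel;
# trials are replayed in block-then-trial order
session_kernel_data <- function(data) {
  data <- data[order(data$block_id, data$trial), , drop = FALSE]
  dem_c <- data$demonstrator_choice
  dem_o <- data$demonstrator_outcome
  list(block_id = as.integer(data$block_id),
       trial = as.integer(data$trial),
       cond = condition_code(data$condition),
       choice = as.integer(data$participant_choice),
       outcome = as.numeric(data$participant_outcome),
       dem_choice = as.integer(ifelse(is.na(dem_c), -1L, dem_c)),
       dem_outcome = as.numeric(ifelse(is.na(dem_o), 0, dem_o)))
}

expand_params <- function(params, model) {
  if (model == "qlearn") {
    qlearn_as_social(params[["alpha"]], params[["beta"]])
  } else if (!is.null(names(params))) {
    as.numeric(params[param_names()])
  } else {
    as.numeric(params)
  }
}

#' Session log-likelihood
#'
#' Sum over trials of the log probability the model's trial-wise policy
#' assigned to the participant's actual choice, replaying imitation biases
#' and observational updates exactly as in [simulate_participant()]. Trial
#' probabilities are floored at 1e-9; the number of floored trials is
#' attached as attribute `"n_floored"`.
#'
#' @param params Named parameter vector (see [log_prior()]).
#' @param data Trial-log data frame for one subject.
#' @param model `"social"` or `"qlearn"`.
#' @return Log-likelihood (<= 0).
#' @export
session_loglik <- function(params, data, model = c("social", "qlearn")) {
  model <- match.arg(model)
  k <- session_kernel_data(data)
  logp <- cpp_session_logp(k$block_id, k$trial, k$cond, k$choice, k$outcome,
                           k$dem_choice, k$dem_outcome,
                           expand_params(params, model), 1e-9)
  structure(sum(logp), n_floored = sum(logp <= log(1e-9)))
}

#' Log posterior (LPP)
#'
#' `session_loglik + sum of log priors`, the quantity maximized by
#' [fit_subject()] and used as the per-subject model-evidence approximation
#' in [bms()].
#'
#' @inheritParams session_loglik
#' @param priors A [prior_spec()].
#' @return The log posterior; `-Inf` outside the prior support.
#' @export
log_posterior <- function(params, data, model = c("social", "qlearn"),
                          priors = prior_spec()) {
  model <- match.arg(model)
  lp <- log_prior(params, model, priors)
  if (!is.finite(lp)) return(-Inf)
  as.numeric(session_loglik(params, data, model)) + lp
}

# ---- MAP fitting ------------------------------------------------------------

# search runs in unbounded space: log for temperatures (capped at 100),
# logit for rates
transform_pars <- function(th, type) {
  x <- numeric(length(th))
  t <- type == "temp"
  x[t] <- log(th[t])
  x[!t] <- qlogis(th[!t])
  x
}
untransform_pars <- function(x, type) {
  th <- numeric(length(x))
  t <- type == "temp"
  th[t] <- exp(x[t])
  th[!t] <- plogis(x[!t])
  th
}

draw_start <- function(type, priors) {
  th <- numeric(length(type))
  is_temp <- type == "temp"
  th[is_temp] <- pmin(pmax(rgamma(sum(is_temp),
                                  shape = priors$temperature_shape,
                                  scale = priors$temperature_scale),
                           0.05), 99)
  th[!is_temp] <- pmin(pmax(rbeta(sum(!is_temp), priors$rate_shape1,
                                  priors$rate_shape2), 0.02), 0.98)
  th
}

#' Fit one subject by maximum a posteriori
#'
#' Maximizes the log posterior ([log_posterior()]) by multi-start bounded
#' quasi-Newton search (L-BFGS-B) in transformed space (log temperatures,
#' logit rates); temperatures are capped at 100. The first start is the
#' prior mean/mode; remaining starts are drawn from the priors, so results
#' are deterministic given the RNG state.
#'
#' @inheritParams log_posterior
#' @param n_restarts Number of optimizer starts (>= 1, default 10).
#' @param control Passed to [optim()] (default `list(maxit = 500)`).
#' @return A list of class `"fit_result"` with elements `params` (named MAP
#'   estimates), `lpp`, `loglik`, `model`, `n_restarts`, `converged`.
#' @export
fit_subject <- function(data, model = c("social", "qlearn"),
                        priors = prior_spec(), n_restarts = 10L,
                        control = list(maxit = 500L)) {
  model <- match.arg(model)
  info <- model_par_info(model)
  type <- info$type
  k <- session_kernel_data(data)
  model_code <- if (model == "qlearn") 1L else 0L
  prior_hyper <- c(priors$temperature_shape, priors$temperature_scale,
                   priors$rate_shape1, priors$rate_shape2)
  nll <- function(x) {
    cpp_nlp(x, model_code, k$block_id, k$trial, k$cond, k$choice,
            k$outcome, k$dem_choice, k$dem_outcome, prior_hyper, 1e-9)
  }
  nll_grad <- function(x) {
    cpp_nlp_grad(x, model_code, k$block_id, k$trial, k$cond, k$choice,
                 k$outcome, k$dem_choice, k$dem_outcome, prior_hyper, 1e-9,
                 1e-5)
  }
  lower <- ifelse(type == "temp", log(1e-3), -15)
  upper <- ifelse(type == "temp", log(100), 15)
  starts <- vector("list", n_restarts)
  starts[[1L]] <- ifelse(type == "temp",
                         priors$temperature_shape * priors$temperature_scale,
                         0.5)
  if (n_restarts > 1L)
    for (i in 2:n_restarts) starts[[i]] <- draw_start(type, priors)
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    x0 <- pmin(pmax(transform_pars(s, type), lower), upper)
    res <- tryCatch(
      optim(x0, nll, gr = nll_grad, method = "L-BFGS-B", lower = lower,
            upper = upper, control = control),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all optimizer restarts failed", call. = FALSE)
  params <- setNames(untransform_pars(best$par, type), info$names)
  loglik <- as.numeric(session_loglik(params, data, model))
  structure(list(params = params,
                 lpp = loglik + log_prior(params, model, priors),
                 loglik = loglik, model = model,
                 n_restarts = as.integer(n_restarts),
                 converged = any_conv),
            class = "fit_result")
}

#' Fit every subject of a cohort
#'
#' @param trials Trial-log data frame with a `subject_id` column.
#' @inheritParams fit_subject
#' @return Named list of [fit_subject()] results, one per subject (in order
#'   of first appearance).
#' @export
fit_cohort <- function(trials, model = c("social", "qlearn"),
                       priors = prior_spec(), n_restarts = 10L) {
  model <- match.arg(model)
  ids <- unique(trials$subject_id)
  fits <- lapply(ids, function(id) {
    fit_subject(trials[trials$subject_id == id, , drop = FALSE], model,
                priors = priors, n_restarts = n_restarts)
  })
  names(fits) <- ids
  fits
}

#' Extract fitted parameters as a data frame
#'
#' @param fits A list of `fit_result` objects (e.g. from [fit_cohort()]).
#' @return Data frame with `subject_id`, one column per parameter, `lpp` and
#'   `loglik`.
#' @export
fit_params <- function(fits) {
  out <- do.call(rbind, lapply(fits, function(f) {
    as.data.frame(as.list(f$params))
  }))
  out <- cbind(subject_id = names(fits), out,
               lpp = vapply(fits, `[[`, numeric(1), "lpp"),
               loglik = vapply(fits, `[[`, numeric(1), "loglik"))
  rownames(out) <- NULL
  out
}

# ---- Bayesian model selection -----------------------------------------------

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet scheme over model frequencies in the population,
#' using per-subject log model evidences (here: LPPs). Returns expected model
#' frequencies (posterior probabilities) and exceedance probabilities (the
#' probability that a model is the most frequent), the latter estimated by
#' Monte-Carlo sampling of the Dirichlet posterior under a fixed seed.
#'
#' @param log_evidence Subjects x models numeric matrix of log evidences;
#'   column names identify the models.
#' @param alpha0 Dirichlet prior pseudo-counts (default 1 per model).
#' @param n_samples Monte-Carlo draws for the exceedance probability
#'   (default 1e5).
#' @param mc_seed Seed for the exceedance Monte-Carlo (restored afterwards).
#' @param tol,max_iter Convergence control of the variational iteration.
#' @return A list of class `"bms_result"` with `model_names`,
#'   `dirichlet_alpha`, `posterior_prob` and `exceedance_prob` (each summing
#'   to 1 across models).
#' @export
bms <- function(log_evidence, alpha0 = NULL, n_samples = 1e5,
                mc_seed = 1234L, tol = 1e-10, max_iter = 500L) {
  log_evidence <- as.matrix(log_evidence)
  if (ncol(log_evidence) < 2L || nrow(log_evidence) < 2L)
    stop("need >= 2 models and >= 2 subjects", call. = FALSE)
  if (any(!is.finite(log_evidence)))
    stop("log evidences must be finite", call. = FALSE)
  m <- ncol(log_evidence)
  model_names <- colnames(log_evidence)
  if (is.null(model_names)) model_names <- paste0("model", seq_len(m))
  if (is.null(alpha0)) alpha0 <- rep(1, m)
  alpha <- alpha0
  for (it in seq_len(max_iter)) {
    ln_u <- sweep(log_evidence, 2L, digamma(alpha) - digamma(sum(alpha)),
                  `+`)
    ln_u <- ln_u - apply(ln_u, 1L, max)
    g <- exp(ln_u)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  xp <- withr::with_seed(mc_seed, {
    draws <- matrix(rgamma(n_samples * m, shape = rep(alpha, each = n_samples)),
                    nrow = n_samples)
    tabulate(max.col(draws, ties.method = "random"), nbins = m) / n_samples
  })
  structure(list(model_names = model_names,
                 dirichlet_alpha = setNames(alpha, model_names),
                 posterior_prob = setNames(alpha / sum(alpha), model_names),
                 exceedance_prob = setNames(xp, model_names)),
            class = "bms_result")
}

# ---- posterior predictive check ---------------------------------------------

#' Posterior predictive check on correct-choice rates
#'
#' For each subject, simulates `reps` fresh sessions (new schedule and new
#' demonstrator each time) from the fitted parameters, averages the correct
#' rate per condition, and correlates simulated with observed rates across
#' subjects, per condition.
#'
#' @param fits Named list of social-model `fit_result`s (names = subject
#'   ids).
#' @param trials Observed trial-log data frame for the same subjects.
#' @param reps Simulations per subject (>= 1).
#' @param config A [task_config()].
#' @return List with `correlations` (named per-condition Pearson r),
#'   `observed` and `simulated` per-subject rate tables.
#' @export
predictive_check <- function(fits, trials, reps = 100L,
                             config = task_config()) {
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  obs <- correct_rates(trials)
  ids <- names(fits)
  sim <- do.call(rbind, lapply(ids, function(id) {
    pars <- fits[[id]]$params
    acc <- 0
    for (r in seq_len(reps))
      acc <- acc + correct_rates(simulate_session(pars, config,
                                                  subject_id = id))[, -1]
    cbind(subject_id = id, acc / reps)
  }))
  obs <- obs[match(ids, obs$subject_id), , drop = FALSE]
  rs <- vapply(conditions(), function(cn) {
    cor(obs[[cn]], sim[[cn]])
  }, numeric(1))
  list(correlations = rs, observed = obs, simulated = sim)
}
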