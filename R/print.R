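#' @method print fit_result
#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("MAP fit (%s model)\n", x$model))
  print(round(x$params, 4))
  cat(sprintf("loglik %.3f, lpp %.3f, %d restarts%s\n", x$loglik, x$lpp,
              x$n_restarts, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @method print bms_result
#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  print(data.frame(model = x$model_names,
                   alpha = round(unname(x$dirichlet_alpha), 2),
                   posterior_prob = round(unname(x$posterior_prob), 4),
                   exceedance_prob = round(unname(x$exceedance_prob), 4)))
  invisible(x)
}

#' @method print cohort
#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects in %d sample(s)%s\n",
              nrow(x$subjects), length(unique(x$subjects$sample_id)),
              if (is.null(x$sessions)) " (scores/parameters only)" else
                sprintf(", %d trials simulated", nrow(x$sessions))))
  invisible(x)
}

#' @method print recovery_matrix
#' @export
print.recovery_matrix <- function(x, ...) {
  cat(sprintf("Parameter recovery (%d datasets x %d subjects)\n",
              x$design$n_datasets, x$design$n_subjects))
  cat("Detection rates (rows manipulated, columns recovered):\n")
  print(round(x$detection_rate, 2))
  cat("Mean recovered correlation (diagonal):\n")
  dg <- vapply(rownames(x$mean_r), function(p) x$mean_r[p, p], numeric(1))
  print(round(dg, 3))
  invisible(x)
}

#' @method print classifier_report
#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("Threshold classifier, %d random half-splits\n", x$n_repeats))
  print(transform(x$summary, mean = round(mean, 3), sem = round(sem, 4)))
  invisible(x)
}

#' @method print meta_result
#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Random-effects meta-analysis (k = %d): effect %.3f [%.3f, %.3f], z = %.2f, p = %.4g, tau2 = %.4f\n",
    x$k, x$effect, x$ci95[1], x$ci95[2], x$z_stat, x$p_value, x$tau2))
  invisible(x)
}

#' @method print correlation_result
#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, t(%d) = %.2f, p = %.4g (n = %d)\n",
              x$r, x$df, x$t_stat, x$p_value, x$n))
  invisible(x)
}
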