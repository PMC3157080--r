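#' Tidy a clinical-performance report
#'
#' Returns the per-risk-group relative-risk table, one row per group, in
#' broom's one-term-per-row convention.
#'
#' @param x A `risk_performance` object from [evaluate_predictions()].
#' @param ... Unused.
#' @return A tibble with columns `group`, `rr`, `ci_low`, `ci_high`,
#'   `events_in`, `n_in`, `events_out`, `n_out`, `continuity_corrected`.
#' @exportS3Method generics::tidy
tidy.risk_performance <- function(x, ...) {
  as_tibble(x$group_risks)
}

#' Glance at a clinical-performance report
#'
#' @param x A `risk_performance` object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `prevalence`, `auc`.
#' @exportS3Method generics::glance
glance.risk_performance <- function(x, ...) {
  tibble(n = x$n, sensitivity = x$confusion$sensitivity,
         specificity = x$confusion$specificity,
         ppv = x$predictive_values$ppv, npv = x$predictive_values$npv,
         prevalence = x$prevalence, auc = x$auc)
}

#' Glance at a cohort risk prediction
#'
#' @param x A `nodal_risk_prediction` tibble.
#' @param ... Unused.
#' @return A one-row tibble with the cohort size, class counts and mean
#'   posterior probability.
#' @exportS3Method generics::glance
glance.nodal_risk_prediction <- function(x, ...) {
  tibble(n = nrow(x), n_low = sum(x$risk_class == "low"),
         n_intermediate = sum(x$risk_class == "intermediate"),
         n_high = sum(x$risk_class == "high"), mean_p = mean(x$p))
}

#' Glance at a fidelity report
#'
#' @param x A `fidelity_report` tibble from [screen_probes()].
#' @param ... Unused.
#' @return A one-row tibble with probe counts by screen outcome.
#' @exportS3Method generics::glance
glance.fidelity_report <- function(x, ...) {
  tibble(n_probes = nrow(x), n_pass = sum(x$pass_overall),
         n_fail_corr = sum(!x$pass_corr), n_fail_diff = sum(!x$pass_diff),
         alpha_corr = attr(x, "alpha_corr"),
         alpha_diff = attr(x, "alpha_diff"))
}

#' ROC curve of a performance report
#'
#' @param object A `risk_performance` object.
#' @param ... Unused.
#' @return A ggplot of the empirical ROC curve with the AUC in the title.
#' @exportS3Method ggplot2::autoplot
autoplot.risk_performance <- function(object, ...) {
  pts <- roc_points(object$scores, object$labels)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - specificity)",
                  y = "True positive rate (sensitivity)",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Posterior-risk distribution of a cohort prediction
#'
#' Histogram of the posterior probabilities with the low/high risk-class
#' thresholds marked.
#'
#' @param object A `nodal_risk_prediction` tibble.
#' @param bins Histogram bin count (default 40).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.nodal_risk_prediction <- function(object, bins = 40, ...) {
  pr <- attr(object, "params")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = c(pr$t_low, pr$t_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Posterior probability of nodal involvement",
                  y = "Samples",
                  title = "Posterior risk distribution",
                  subtitle = sprintf("thresholds: low < %g, high > %g",
                                     pr$t_low, pr$t_high)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.risk_performance
#' @param performance A `risk_performance` object.
#' @export
plot_roc <- function(performance, ...) autoplot(performance, ...)
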