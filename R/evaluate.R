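#' Confusion metrics for risk-class predictions
#'
#' Dichotomises the three risk classes into a binary test and tabulates it
#' against pathological nodal status. By default only the `high` class is
#' test-positive (intermediate and low count as negative); set
#' `positive = "high_or_intermediate"` to move the cut. With single-class
#' labels the rate for the absent class is `NA` (undefined), never 0.
#'
#' @param risk_class Factor or character vector of per-sample risk classes
#'   (`low`/`intermediate`/`high`), or logical/binary test results.
#' @param labels Binary nodal outcomes (0/1) aligned with `risk_class`.
#' @param positive Which classes count as test-positive.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_metrics <- function(risk_class, labels,
                              positive = c("high", "high_or_intermediate")) {
  positive <- match.arg(positive)
  if (length(risk_class) == 0 || length(risk_class) != length(labels)) {
    stop_input("`risk_class` and `labels` must be non-empty and aligned.",
               "noderisk_input_error")
  }
  y <- as.integer(labels)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop_input("`labels` must be binary 0/1.", "noderisk_input_error")
  }
  test_pos <- dichotomize(risk_class, positive)
  tp <- sum(test_pos & y == 1L)
  fp <- sum(test_pos & y == 0L)
  tn <- sum(!test_pos & y == 0L)
  fn <- sum(!test_pos & y == 1L)
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

dichotomize <- function(risk_class, positive) {
  if (is.logical(risk_class)) return(risk_class)
  if (is.numeric(risk_class) && all(risk_class %in% c(0, 1))) {
    return(risk_class == 1)
  }
  cls <- as.character(risk_class)
  ok <- c("low", "intermediate", "high")
  if (!all(cls %in% ok)) {
    stop_input(sprintf("Unknown risk class value(s): %s",
                       toString(setdiff(unique(cls), ok))),
               "noderisk_input_error")
  }
  if (positive == "high") cls == "high" else cls %in% c("high", "intermediate")
}

#' Prevalence-adjusted predictive values by Bayes' rule
#'
#' Converts sensitivity and specificity into positive and negative
#' predictive values at an assumed disease prevalence:
#' `PPV = se * pi / (se * pi + (1 - sp) * (1 - pi))` and
#' `NPV = sp * (1 - pi) / (sp * (1 - pi) + (1 - se) * pi)`.
#' Predictive values, unlike sensitivity and specificity, depend on the
#' population tested: at the 23% prevalence of nodal involvement at
#' cystectomy a test with se 0.44 / sp 0.70 gives PPV 0.30 and NPV 0.81,
#' while restricting testing to T3 tumours (prevalence 39%) moves them to
#' 0.48 and 0.66.
#'
#' @param sensitivity,specificity,prevalence Probabilities in `[0, 1]`.
#' @return A one-row tibble with columns `ppv`, `npv`, `prevalence`.
#' @export
#' @examples
#' ppv_npv_at_prevalence(0.44, 0.70, 0.23)
ppv_npv_at_prevalence <- function(sensitivity, specificity, prevalence) {
  args <- c(sensitivity = sensitivity, specificity = specificity,
            prevalence = prevalence)
  if (anyNA(args) || any(args < 0 | args > 1)) {
    stop_input("sensitivity, specificity and prevalence must be in [0, 1].",
               "noderisk_domain_error")
  }
  d_ppv <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  d_npv <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  if (d_ppv == 0 || d_npv == 0) {
    stop_input("Degenerate denominator: predictive value undefined at this prevalence.",
               "noderisk_domain_error")
  }
  tibble(ppv = sensitivity * prevalence / d_ppv,
         npv = specificity * (1 - prevalence) / d_npv,
         prevalence = prevalence)
}

#' Relative risk of nodal involvement for a risk group
#'
#' Ratio of the outcome rate inside the group to the rate in a comparator:
#' the group's complement (default, the standard epidemiological RR) or the
#' whole cohort. The 95% CI uses the Katz log-normal approximation,
#' `exp(log(RR) +/- 1.96 * sqrt(1/a - 1/n_in + 1/c - 1/n_out))` with `a`,
#' `c` the event counts in and out of the group. When either arm has zero
#' events the point estimate or CI is undefined; a Haldane continuity
#' correction (0.5 added to every cell) is then applied and flagged.
#'
#' @param in_group Logical (or 0/1) group membership per sample.
#' @param labels Binary nodal outcomes aligned with `in_group`.
#' @param conf_level Confidence level for the CI (default 0.95).
#' @param reference `"complement"` (default) or `"cohort"`.
#' @return A one-row tibble: `rr`, `ci_low`, `ci_high`, `events_in`, `n_in`,
#'   `events_out`, `n_out`, `continuity_corrected`.
#' @export
relative_risk <- function(in_group, labels, conf_level = 0.95,
                          reference = c("complement", "cohort")) {
  reference <- match.arg(reference)
  g <- as.logical(in_group)
  y <- as.integer(labels)
  if (length(g) != length(y) || anyNA(g) || anyNA(y) ||
      !all(y %in% c(0L, 1L))) {
    stop_input("`in_group` and `labels` must be aligned logical / binary vectors.",
               "noderisk_input_error")
  }
  if (!any(g) || all(g)) {
    stop_input("Need at least one sample inside and outside the group.",
               "noderisk_input_error")
  }
  out_idx <- if (reference == "complement") !g else rep(TRUE, length(g))
  a <- sum(y[g]); n_in <- sum(g)
  c_ <- sum(y[out_idx]); n_out <- sum(out_idx)
  cc <- a == 0 || c_ == 0
  if (cc) {
    a <- a + 0.5; c_ <- c_ + 0.5; n_in <- n_in + 1; n_out <- n_out + 1
  }
  rr <- (a / n_in) / (c_ / n_out)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a - 1 / n_in + 1 / c_ - 1 / n_out)
  tibble(rr = rr, ci_low = rr * exp(-z * se), ci_high = rr * exp(z * se),
         events_in = sum(as.integer(labels)[as.logical(in_group)]),
         n_in = sum(as.logical(in_group)),
         events_out = sum(as.integer(labels)[out_idx]),
         n_out = sum(out_idx), continuity_corrected = cc)
}

#' ROC area under the curve
#'
#' AUC as the Mann-Whitney probability that a random node-positive sample
#' outscores a random node-negative one, with ties counted half:
#' `P(s+ > s-) + P(s+ = s-) / 2`. Computed from the rank-sum identity, so it
#' is exact for tied scores and equals exhaustive pair counting.
#'
#' @param scores Numeric risk scores (e.g. posterior probabilities).
#' @param labels Binary outcomes aligned with `scores`; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  if (!is.numeric(scores) || length(scores) != length(y) || anyNA(scores) ||
      anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop_input("`scores` and `labels` must be aligned numeric / binary vectors.",
               "noderisk_input_error")
  }
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) {
    stop_input("Both outcome classes must be present to compute AUC.",
               "noderisk_input_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full clinical-performance report for risk predictions
#'
#' Assembles the confusion summary (high-risk = test-positive by default),
#' prevalence-adjusted PPV/NPV, ROC AUC of the posterior probabilities, and
#' per-risk-group relative risks with 95% CIs. Sensitivity and specificity
#' come from the evaluated cohort; `prevalence` (default 0.23, overridable
#' e.g. to 0.39 for T3-only testing) only enters the predictive-value
#' conversion.
#'
#' @param predictions A `nodal_risk_prediction` tibble (or any tibble with
#'   `sample_id`, `p`, `risk_class`).
#' @param labels Binary nodal outcomes: a tibble with `sample_id` and
#'   `node_status`, or a vector aligned with `predictions`.
#' @param prevalence Assumed prevalence for the PPV/NPV conversion.
#' @param positive Dichotomisation rule, see [confusion_metrics()].
#' @param rr_reference RR comparator, see [relative_risk()].
#' @return An object of class `risk_performance`: a list with elements
#'   `confusion`, `predictive_values`, `auc`, `group_risks`, `n`,
#'   `prevalence`. Use [tidy()] / [glance()] / [autoplot()] on it.
#' @export
evaluate_predictions <- function(predictions, labels, prevalence = 0.23,
                                 positive = c("high", "high_or_intermediate"),
                                 rr_reference = c("complement", "cohort")) {
  positive <- match.arg(positive)
  rr_reference <- match.arg(rr_reference)
  if (!is.data.frame(predictions) ||
      !all(c("sample_id", "p", "risk_class") %in% names(predictions))) {
    stop_input("`predictions` needs columns sample_id, p, risk_class.",
               "noderisk_input_error")
  }
  if (nrow(predictions) == 0) {
    stop_input("Empty predictions.", "noderisk_input_error")
  }
  y <- align_labels(labels, predictions$sample_id)
  conf <- confusion_metrics(predictions$risk_class, y, positive = positive)
  pv <- if (!anyNA(c(conf$sensitivity, conf$specificity))) {
    # a one-sided cohort (e.g. no test-negatives) makes a predictive value
    # genuinely undefined; report NA rather than fail the whole report
    tryCatch(
      ppv_npv_at_prevalence(conf$sensitivity, conf$specificity, prevalence),
      noderisk_domain_error = function(e) {
        tibble(ppv = NA_real_, npv = NA_real_, prevalence = prevalence)
      })
  } else {
    tibble(ppv = NA_real_, npv = NA_real_, prevalence = prevalence)
  }
  auc <- if (length(unique(y)) == 2) roc_auc(predictions$p, y) else NA_real_
  cls <- as.character(predictions$risk_class)
  group_risks <- list_rbind(map(c("low", "intermediate", "high"), function(g) {
    in_g <- cls == g
    if (!any(in_g) || all(in_g)) {
      return(tibble(group = g, rr = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, events_in = sum(y[in_g]),
                    n_in = sum(in_g), events_out = sum(y[!in_g]),
                    n_out = sum(!in_g), continuity_corrected = NA))
    }
    dplyr::bind_cols(tibble(group = g),
                     relative_risk(in_g, y, reference = rr_reference))
  }))
  structure(list(confusion = conf, predictive_values = pv, auc = auc,
                 group_risks = group_risks, n = nrow(predictions),
                 prevalence = prevalence, positive = positive,
                 rr_reference = rr_reference,
                 scores = predictions$p, labels = y),
            class = "risk_performance")
}

#' @export
print.risk_performance <- function(x, ...) {
  cat("Clinical performance of nodal-risk predictions\n")
  cat(sprintf("  n = %d samples, %d node-positive (observed prevalence %.3f)\n",
              x$n, sum(x$labels), mean(x$labels)))
  cat(sprintf("  sensitivity = %.3f, specificity = %.3f (test-positive = %s)\n",
              x$confusion$sensitivity, x$confusion$specificity, x$positive))
  cat(sprintf("  PPV = %.3f, NPV = %.3f at assumed prevalence %.2f\n",
              x$predictive_values$ppv, x$predictive_values$npv, x$prevalence))
  cat(sprintf("  ROC AUC = %.3f\n", x$auc))
  cat(sprintf("  relative risks (vs %s):\n", x$rr_reference))
  for (i in seq_len(nrow(x$group_risks))) {
    g <- x$group_risks[i, ]
    cat(sprintf("    %-12s RR = %s (95%% CI %s - %s), %d/%d events\n",
                g$group, fmt_or_na(g$rr), fmt_or_na(g$ci_low),
                fmt_or_na(g$ci_high), g$events_in, g$n_in))
  }
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)

#' ROC curve points for a set of scores
#'
#' Returns the empirical ROC curve (one point per distinct score threshold)
#' for plotting or export.
#'
#' @inheritParams roc_auc
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  y <- as.integer(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  list_rbind(map(thr, function(t) {
    tibble(threshold = t,
           fpr = mean(scores[y == 0L] >= t),
           tpr = mean(scores[y == 1L] >= t))
  }))
}
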