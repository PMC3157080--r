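#' Spearman rank correlation between two profiles
#'
#' Rank correlation with average (fractional) ranks for ties; equal to the
#' Pearson correlation of the rank vectors. This is the similarity measure
#' the nearest-neighbour risk score is built on, so it is exposed directly.
#'
#' @param x,y Numeric vectors of equal length >= 2, each with at least two
#'   distinct values.
#' @return The correlation, in `[-1, 1]`.
#' @export
#' @examples
#' spearman_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
spearman_correlation <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop_input("`x` and `y` must be numeric vectors of equal length.",
               "noderisk_input_error")
  }
  if (length(x) < 2) {
    stop_input("Need at least 2 observations.",
               "noderisk_insufficient_data_error")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop_input("Constant vector: rank correlation is undefined.",
               "noderisk_degenerate_error")
  }
  stats::cor(x, y, method = "spearman")
}

#' Posterior probability of nodal involvement for one profile
#'
#' Bayesian weighted nearest-neighbour risk score. The query's Spearman
#' correlation `rho_i` with every reference profile is computed over the
#' panel probes; the `k` most-correlated references are retained (all when
#' `k = 0`, samples tied with the k-th correlation included); each retained
#' reference gets weight `w_i = max(rho_i, 0)^gamma` (negative correlations
#' contribute nothing); and the posterior is the pseudo-count-smoothed
#' weighted mean of the binary nodal labels,
#' `p = (s * pi0 + sum(w_i * y_i)) / (s + sum(w_i))`,
#' with prior mass `s` at the baseline prevalence `pi0`. When no reference
#' receives positive weight the score falls back to the prior `pi0` (the
#' `prior_fallback` flag is set).
#'
#' @param query Numeric vector over the panel probes, in reference probe
#'   order (names, if present, must match the reference probes).
#' @param reference Expression tibble of the labelled reference cohort,
#'   restricted to the panel.
#' @param labels Binary nodal labels for the reference: a tibble with
#'   `sample_id` and `node_status` columns, or a vector (named by sample ID,
#'   or in reference row order).
#' @param k Neighbour count; `0` (default) uses every reference sample.
#' @param gamma Weight exponent applied to positive correlations (default 1).
#' @param prior_strength Pseudo-count mass `s` on the baseline prior
#'   (default 1).
#' @param baseline_prevalence Prior probability `pi0` of nodal involvement
#'   (default 0.23, the prevalence at cystectomy).
#' @param detail If `TRUE`, attach a `neighbors` attribute: a tibble of
#'   per-reference `sample_id`, `rho`, `weight`, `used`.
#' @return A one-row tibble with columns `p` and `prior_fallback`.
#' @export
posterior_risk <- function(query, reference, labels, k = 0, gamma = 1,
                           prior_strength = 1, baseline_prevalence = 0.23,
                           detail = FALSE) {
  reference <- validate_expression(reference, "reference")
  probes <- probe_cols(reference)
  if (length(query) != length(probes)) {
    stop_input(sprintf("Query has %d values but the panel has %d probes.",
                       length(query), length(probes)),
               "noderisk_input_error")
  }
  if (!is.null(names(query)) && !identical(names(query), probes)) {
    stop_input("Query names do not match reference probes in order.",
               "noderisk_input_error")
  }
  if (length(unique(query)) < 2) {
    stop_input("Constant query profile: rank correlation is undefined.",
               "noderisk_degenerate_error")
  }
  y <- align_labels(labels, reference$sample_id)
  check_predictor_params(k, gamma, prior_strength, baseline_prevalence)
  rho <- unname(drop(stats::cor(t(expr_matrix(reference)), query,
                                method = "spearman")))
  res <- weighted_posterior(rho, y, k, gamma, prior_strength,
                            baseline_prevalence)
  out <- tibble(p = res$p, prior_fallback = res$prior_fallback)
  if (detail) {
    attr(out, "neighbors") <- tibble(sample_id = reference$sample_id,
                                     rho = rho, weight = res$weight,
                                     used = res$used)
  }
  out
}

# Core weighting rule shared by posterior_risk() and predict_nodal_risk().
weighted_posterior <- function(rho, y, k, gamma, s, pi0) {
  rho <- unname(rho)
  n <- length(rho)
  used <- rep(TRUE, n)
  if (k > 0 && k < n) {
    # retain all samples tied with the k-th correlation (deterministic cut);
    # sort() drops NA correlations (degenerate reference profiles)
    srt <- sort(rho, decreasing = TRUE)
    if (length(srt) > 0) {
      cutoff <- srt[min(k, length(srt))]
      used <- !is.na(rho) & rho >= cutoff
    }
  }
  w <- numeric(n)
  pos <- used & !is.na(rho) & rho > 0
  w[pos] <- rho[pos]^gamma
  sw <- sum(w)
  p <- if (sw == 0 && s == 0) pi0 else (s * pi0 + sum(w * y)) / (s + sw)
  list(p = p, prior_fallback = sw == 0, weight = w, used = used)
}

check_predictor_params <- function(k, gamma, prior_strength, pi0) {
  stopifnot(k >= 0, k == as.integer(k), gamma >= 0, prior_strength >= 0,
            pi0 > 0, pi0 < 1)
}

align_labels <- function(labels, sample_ids) {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "node_status") %in% names(labels))) {
      stop_input("Label table needs `sample_id` and `node_status` columns.",
                 "noderisk_input_error")
    }
    if (!setequal(labels$sample_id, sample_ids) ||
        nrow(labels) != length(sample_ids)) {
      stop_input("Labels must cover exactly the reference samples.",
                 "noderisk_input_error")
    }
    y <- labels$node_status[match(sample_ids, labels$sample_id)]
  } else if (!is.null(names(labels))) {
    if (!setequal(names(labels), sample_ids) ||
        length(labels) != length(sample_ids)) {
      stop_input("Named labels must cover exactly the reference samples.",
                 "noderisk_input_error")
    }
    y <- unname(labels[match(sample_ids, names(labels))])
  } else {
    if (length(labels) != length(sample_ids)) {
      stop_input("Labels must have one entry per reference sample.",
                 "noderisk_input_error")
    }
    y <- labels
  }
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop_input("Nodal labels must be binary 0/1.", "noderisk_input_error")
  }
  y
}

#' Stratify a posterior risk probability into risk classes
#'
#' Three-tier stratification around the baseline prevalence: `high` when
#' `p > t_high`, `low` when `p < t_low`, and `intermediate` on the closed
#' interval `t_low <= p <= t_high`. Defaults are the published thresholds
#' 0.227 and 0.247 bracketing the 23% baseline prevalence.
#'
#' @param p Numeric vector of posterior probabilities in `[0, 1]`.
#' @param t_low,t_high Class boundaries, `0 < t_low <= t_high < 1`.
#' @return A factor with levels `low`, `intermediate`, `high`.
#' @export
#' @examples
#' classify_risk(c(0.30, 0.247, 0.227, 0.10))
classify_risk <- function(p, t_low = 0.227, t_high = 0.247) {
  stopifnot(t_low > 0, t_low <= t_high, t_high < 1)
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop_input("`p` must be probabilities in [0, 1].", "noderisk_domain_error")
  }
  cls <- ifelse(p > t_high, "high", ifelse(p < t_low, "low", "intermediate"))
  factor(cls, levels = c("low", "intermediate", "high"))
}

#' Predict nodal-involvement risk for a cohort of query profiles
#'
#' Batch application of [posterior_risk()] and [classify_risk()] to every
#' sample of a query expression matrix. Query and reference probes must
#' match exactly, in order; no silent reordering is performed. With
#' `leave_one_out = TRUE` each query is scored against the reference with
#' any reference sample of the same `sample_id` excluded, which is the
#' honest way to evaluate the reference cohort on itself.
#'
#' @param queries Expression tibble of query samples, restricted to the
#'   panel (see [subset_to_panel()]).
#' @param reference,labels,k,gamma,prior_strength,baseline_prevalence As in
#'   [posterior_risk()].
#' @param t_low,t_high Risk-class thresholds (defaults 0.227 / 0.247), see
#'   [classify_risk()].
#' @param leave_one_out Exclude the query's own sample ID from the
#'   reference pool.
#' @return A tibble of class `nodal_risk_prediction` with one row per query:
#'   `sample_id`, `p`, `risk_class`, `prior_fallback`.
#' @export
predict_nodal_risk <- function(queries, reference, labels, k = 0, gamma = 1,
                               prior_strength = 1, baseline_prevalence = 0.23,
                               t_low = 0.227, t_high = 0.247,
                               leave_one_out = FALSE) {
  queries <- validate_expression(queries, "queries")
  reference <- validate_expression(reference, "reference")
  if (!identical(probe_cols(queries), probe_cols(reference))) {
    stop_input("Query and reference probes must match exactly, in order (no silent reordering).",
               "noderisk_probe_order_error")
  }
  check_predictor_params(k, gamma, prior_strength, baseline_prevalence)
  y <- align_labels(labels, reference$sample_id)
  qm <- expr_matrix(queries)
  const <- apply(qm, 1, function(v) length(unique(v)) < 2)
  if (any(const)) {
    stop_input(sprintf("Constant query profile(s): %s",
                       toString(rownames(qm)[const])),
               "noderisk_degenerate_error")
  }
  # n_ref x n_query Spearman correlations in one pass
  rho_mat <- suppressWarnings(
    stats::cor(t(expr_matrix(reference)), t(qm), method = "spearman"))
  rows <- map(seq_len(nrow(queries)), function(i) {
    rho <- rho_mat[, i]
    keep <- rep(TRUE, length(rho))
    if (leave_one_out) keep <- reference$sample_id != queries$sample_id[i]
    res <- weighted_posterior(rho[keep], y[keep], k, gamma, prior_strength,
                              baseline_prevalence)
    tibble(sample_id = queries$sample_id[i], p = res$p,
           prior_fallback = res$prior_fallback)
  })
  out <- list_rbind(rows)
  out$risk_class <- classify_risk(out$p, t_low, t_high)
  out <- out[, c("sample_id", "p", "risk_class", "prior_fallback")]
  attr(out, "params") <- list(k = k, gamma = gamma,
                              prior_strength = prior_strength,
                              baseline_prevalence = baseline_prevalence,
                              t_low = t_low, t_high = t_high,
                              leave_one_out = leave_one_out)
  class(out) <- c("nodal_risk_prediction", class(out))
  out
}

#' @export
print.nodal_risk_prediction <- function(x, ...) {
  pr <- attr(x, "params")
  cat(sprintf(
    "<nodal_risk_prediction: %d samples; low/intermediate/high = %d/%d/%d; pi0 = %g>\n",
    nrow(x), sum(x$risk_class == "low"), sum(x$risk_class == "intermediate"),
    sum(x$risk_class == "high"), pr$baseline_prevalence))
  NextMethod()
}
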