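#' Paired FFPE/fresh-frozen concordance test for one probe
#'
#' Tests whether a probe's expression is positively correlated across matched
#' formalin-fixed (FFPE) and fresh-frozen (FF) preparations of the same
#' tumours. Pairs are matched by `sample_id`; the one-tailed p-value tests
#' H0: r <= 0 against H1: r > 0 via the t-transform of the correlation at
#' n - 2 degrees of freedom. Pearson correlation of the log-scale values is
#' the default; `method = "spearman"` uses rank correlation instead.
#'
#' @param ffpe,ff Expression tibbles with identical sample-ID sets.
#' @param probe_id Probe to test; must be present in both matrices.
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble with columns `probe_id`, `r`, `p_one_tailed`,
#'   `n_pairs`.
#' @export
paired_correlation_test <- function(ffpe, ff, probe_id,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ffpe <- validate_expression(ffpe, "ffpe")
  ff <- validate_expression(ff, "ff")
  if (!setequal(ffpe$sample_id, ff$sample_id)) {
    stop_input("FFPE and FF matrices must contain the same sample IDs (matched pairs).",
               "noderisk_pairing_error")
  }
  check_probe(ffpe, probe_id, "ffpe")
  check_probe(ff, probe_id, "ff")
  ff <- ff[match(ffpe$sample_id, ff$sample_id), ]
  x <- ffpe[[probe_id]]
  y <- ff[[probe_id]]
  n <- length(x)
  if (n < 3) {
    stop_input("Need at least 3 matched pairs.", "noderisk_insufficient_data_error")
  }
  res <- pair_corr_core(x, y, method)
  if (is.null(res)) {
    stop_input(sprintf("Probe '%s' has zero variance in one preparation.",
                       probe_id), "noderisk_degenerate_error")
  }
  tibble(probe_id = probe_id, r = res$r, p_one_tailed = res$p, n_pairs = n)
}

# Correlation criterion on pre-paired vectors; NULL when degenerate.
pair_corr_core <- function(x, y, method) {
  if (var_zero(x) || var_zero(y)) return(NULL)
  ct <- stats::cor.test(x, y, alternative = "greater", method = method,
                        exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value)
}

# Welch criterion on the two group vectors, with the constant-data rule.
equiv_core <- function(x, y) {
  if (var_zero(x) && var_zero(y)) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Specimen-source equivalence test for one probe
#'
#' Two-tailed Welch two-sample t-test for a difference in a probe's mean
#' expression between independent transurethral-resection (TUR) and
#' cystectomy specimen groups. A probe survives the screen when the test
#' fails to reject, i.e. its expression is statistically indistinguishable
#' between the specimen sources.
#'
#' @param tur,cyst Expression tibbles for the two independent groups.
#' @param probe_id Probe to test; must be present in both matrices.
#' @return A one-row tibble with columns `probe_id`, `mean_diff`,
#'   `p_two_tailed`, `n_tur`, `n_cyst`.
#' @export
specimen_equivalence_test <- function(tur, cyst, probe_id) {
  tur <- validate_expression(tur, "tur")
  cyst <- validate_expression(cyst, "cyst")
  check_probe(tur, probe_id, "tur")
  check_probe(cyst, probe_id, "cyst")
  x <- tur[[probe_id]]
  y <- cyst[[probe_id]]
  if (length(x) < 2 || length(y) < 2) {
    stop_input("Each specimen group needs at least 2 samples.",
               "noderisk_insufficient_data_error")
  }
  # equiv_core handles constant data explicitly: identical constants are a
  # perfect non-difference (p = 1), distinct constants a certain one (p = 0)
  tibble(probe_id = probe_id, mean_diff = mean(x) - mean(y),
         p_two_tailed = equiv_core(x, y), n_tur = length(x),
         n_cyst = length(y))
}

#' Screen probes for preservation and specimen-source fidelity
#'
#' Applies the high-fidelity probe screen: a probe passes when (a) its
#' FFPE/FF paired correlation is significantly greater than zero at
#' `alpha_corr` (one-tailed) and (b) its expression is not significantly
#' different between TUR and cystectomy specimens at `alpha_diff`
#' (two-tailed). The two criteria are conjoined; no multiple-testing
#' correction is applied across probes. Probes with degenerate data
#' (zero variance) fail automatically with a reason code rather than
#' raising an error.
#'
#' @param ffpe,ff Matched-pair expression tibbles (same sample IDs).
#' @param tur,cyst Independent specimen-group expression tibbles.
#' @param probes Character vector of probe IDs to screen; defaults to all
#'   probes common to the four matrices.
#' @param alpha_corr One-tailed significance level for the correlation
#'   criterion (default 0.025).
#' @param alpha_diff Two-tailed significance level for the difference
#'   criterion (default 0.01).
#' @param method Correlation type passed to [paired_correlation_test()].
#' @return A `fidelity_report` tibble with one row per probe: `probe_id`,
#'   `r`, `p_one_tailed`, `p_two_tailed`, `pass_corr`, `pass_diff`,
#'   `pass_overall`, `reason`.
#' @export
screen_probes <- function(ffpe, ff, tur, cyst, probes = NULL,
                          alpha_corr = 0.025, alpha_diff = 0.01,
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(alpha_corr > 0, alpha_corr < 1, alpha_diff > 0, alpha_diff < 1)
  ffpe <- validate_expression(ffpe, "ffpe")
  ff <- validate_expression(ff, "ff")
  tur <- validate_expression(tur, "tur")
  cyst <- validate_expression(cyst, "cyst")
  if (is.null(probes)) {
    probes <- Reduce(intersect, list(probe_cols(ffpe), probe_cols(ff),
                                     probe_cols(tur), probe_cols(cyst)))
  }
  for (m in list(ffpe = ffpe, ff = ff, tur = tur, cyst = cyst)) {
    missing <- setdiff(probes, probe_cols(m))
    if (length(missing) > 0) {
      stop_input(sprintf("Probe(s) absent from an input matrix: %s",
                         toString(missing)), "noderisk_missing_probe_error")
    }
  }
  if (!setequal(ffpe$sample_id, ff$sample_id)) {
    stop_input("FFPE and FF matrices must contain the same sample IDs (matched pairs).",
               "noderisk_pairing_error")
  }
  if (nrow(ffpe) < 3) {
    stop_input("Need at least 3 matched pairs.",
               "noderisk_insufficient_data_error")
  }
  if (nrow(tur) < 2 || nrow(cyst) < 2) {
    stop_input("Each specimen group needs at least 2 samples.",
               "noderisk_insufficient_data_error")
  }
  ff <- ff[match(ffpe$sample_id, ff$sample_id), ]
  rows <- map(probes, function(p) {
    r <- NA_real_; p1 <- NA_real_; reason <- NA_character_
    res <- pair_corr_core(ffpe[[p]], ff[[p]], method)
    if (is.null(res)) {
      reason <- "degenerate_pair_variance"
    } else {
      r <- res$r; p1 <- res$p
    }
    p2 <- equiv_core(tur[[p]], cyst[[p]])
    pass_corr <- !is.na(p1) && p1 < alpha_corr
    pass_diff <- !is.na(p2) && p2 >= alpha_diff
    tibble(probe_id = p, r = r, p_one_tailed = p1, p_two_tailed = p2,
           pass_corr = pass_corr, pass_diff = pass_diff,
           pass_overall = pass_corr && pass_diff, reason = reason)
  })
  out <- list_rbind(rows)
  attr(out, "alpha_corr") <- alpha_corr
  attr(out, "alpha_diff") <- alpha_diff
  class(out) <- c("fidelity_report", class(out))
  out
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat(sprintf(
    "<fidelity_report: %d probes screened, %d high-fidelity (alpha_corr = %g, alpha_diff = %g)>\n",
    nrow(x), sum(x$pass_overall), attr(x, "alpha_corr"),
    attr(x, "alpha_diff")))
  NextMethod()
}

check_probe <- function(x, probe_id, arg) {
  if (!(is.character(probe_id) && length(probe_id) == 1 &&
        probe_id %in% probe_cols(x))) {
    stop_input(sprintf("Probe '%s' not found in `%s`.",
                       as.character(probe_id)[1], arg),
               "noderisk_missing_probe_error")
  }
}

var_zero <- function(v) {
  isTRUE(all.equal(stats::var(v), 0)) || stats::var(v) == 0
}
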