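# Shared fixture builders (all fixtures are generated in code).

# Expression tibble from a samples x probes matrix.
expr_tbl <- function(m, sample_ids = sprintf("s%d", seq_len(nrow(m))),
                     probe_ids = sprintf("P%d", seq_len(ncol(m)))) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  names(out) <- probe_ids
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids), out)
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Risk-class predictions realising given confusion counts, with posterior
# probabilities consistent with the class (high > 0.247, low < 0.227).
predictions_with_counts <- function(tp, fn, tn, fp) {
  cls <- c(rep("high", tp), rep("low", fn), rep("low", tn), rep("high", fp))
  y <- c(rep(1L, tp + fn), rep(0L, tn + fp))
  n <- length(cls)
  tibble::tibble(
    sample_id = sprintf("s%d", seq_len(n)),
    p = ifelse(cls == "high", 0.30, 0.10) + seq_len(n) * 1e-4,
    risk_class = factor(cls, levels = c("low", "intermediate", "high")),
    node_status = y)
}

# Brute-force AUC over all positive-negative pairs (independent oracle).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}
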