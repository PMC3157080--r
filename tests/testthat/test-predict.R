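test_that("spearman_correlation matches the rank-difference formula and handles ties", {
  expect_equal(spearman_correlation(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_correlation(1:3, c(3, 2, 1)), -1)
  expect_equal(spearman_correlation(1:4, c(2, 1, 4, 3)), 0.6)

  # oracle on tie-free instances: rho = 1 - 6 * sum(d^2) / (n (n^2 - 1))
  withr::local_seed(101)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- sample(seq_len(n) * 10)
    y <- sample(seq_len(n) * 3)
    d <- rank(x) - rank(y)
    expect_equal(spearman_correlation(x, y),
                 1 - 6 * sum(d^2) / (n * (n^2 - 1)))
  }

  # with ties: equals Pearson correlation of average ranks
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- sample(1:5, n, replace = TRUE) + 0.5
    y <- sample(1:5, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_correlation(x, y), cor(rank(x), rank(y)))
  }

  expect_error(spearman_correlation(rep(1, 5), 1:5),
               class = "noderisk_degenerate_error")
  expect_error(spearman_correlation(1:3, 1:4),
               class = "noderisk_input_error")
})

test_that("posterior_risk implements the smoothed weighted label mean", {
  # references are rank permutations of the query with exactly known
  # Spearman correlations 0.8, 0.4, 0.2 (sum d^2 = 2, 6, 8 at n = 4)
  reference <- expr_tbl(rbind(c(1, 2, 4, 3),
                              c(1, 4, 2, 3),
                              c(1, 4, 3, 2)),
                        sample_ids = c("r1", "r2", "r3"),
                        probe_ids = sprintf("P%d", 1:4))
  query <- c(1, 2, 3, 4)
  labels <- c(r1 = 1, r2 = 0, r3 = 1)
  rho <- apply(rbind(c(1, 2, 4, 3), c(1, 4, 2, 3), c(1, 4, 3, 2)), 1,
               cor, y = query, method = "spearman")
  expect_equal(rho, c(0.8, 0.4, 0.2))

  res <- posterior_risk(query, reference, labels, prior_strength = 0,
                        detail = TRUE)
  expect_equal(res$p, (0.8 + 0.2) / (0.8 + 0.4 + 0.2))
  expect_false(res$prior_fallback)
  nb <- attr(res, "neighbors")
  expect_equal(nb$weight, c(0.8, 0.4, 0.2))

  # prior smoothing: s = 1, pi0 = 0.23
  res1 <- posterior_risk(query, reference, labels, prior_strength = 1,
                         baseline_prevalence = 0.23)
  expect_equal(res1$p, (0.23 + 1.0) / (1 + 1.4))

  # gamma reweighting
  res2 <- posterior_risk(query, reference, labels, prior_strength = 0,
                         gamma = 2)
  expect_equal(res2$p, (0.64 + 0.04) / (0.64 + 0.16 + 0.04))
})

test_that("posterior_risk degenerate branches: no positive evidence and prior fallback", {
  reference <- expr_tbl(rbind(c(1, 2, 3, 4), c(2, 1, 4, 3)),
                        sample_ids = c("r1", "r2"),
                        probe_ids = sprintf("P%d", 1:4))
  # cohort entirely node-negative, s = 0 -> p = 0
  expect_equal(posterior_risk(c(1, 2, 3, 4), reference, c(0, 0),
                              prior_strength = 0)$p, 0)

  # query anti-correlated with every reference -> prior fallback p = pi0
  anti <- c(4, 3, 2, 1)
  for (s in c(0, 1, 5)) {
    res <- posterior_risk(anti, reference,
                          c(1, 1), prior_strength = s,
                          baseline_prevalence = 0.23)
    expect_equal(res$p, 0.23)
    expect_true(res$prior_fallback)
  }

  expect_error(posterior_risk(c(1, 2, 3), reference, c(0, 1)),
               class = "noderisk_input_error")
  expect_error(posterior_risk(rep(1, 4), reference, c(0, 1)),
               class = "noderisk_degenerate_error")
})

test_that("classify_risk reproduces the printed inequalities including the closed interval", {
  expect_equal(as.character(classify_risk(0.30)), "high")
  expect_equal(as.character(classify_risk(0.247)), "intermediate")
  expect_equal(as.character(classify_risk(0.227)), "intermediate")
  expect_equal(as.character(classify_risk(0)), "low")
  expect_error(classify_risk(1.2), class = "noderisk_domain_error")

  # classes partition [0,1]
  p <- seq(0, 1, by = 0.001)
  cls <- classify_risk(p)
  expect_false(anyNA(cls))
  expect_true(all((cls == "high") == (p > 0.247)))
  expect_true(all((cls == "low") == (p < 0.227)))
  expect_true(all((cls == "intermediate") == (p >= 0.227 & p <= 0.247)))
})

test_that("batch prediction is consistent with single-sample composition", {
  cohort <- simulate_cohort(sim_config(n_samples = 40, seed = 5))
  query <- cohort$expression[1, ]
  batch <- predict_nodal_risk(query, cohort$expression, cohort$labels)
  single <- posterior_risk(as.numeric(query[, -1]), cohort$expression,
                           cohort$labels)
  expect_equal(batch$p, single$p)
  expect_equal(batch$risk_class, classify_risk(single$p))
})

test_that("probe mismatch and reordering are rejected, not silently fixed", {
  cohort <- simulate_cohort(sim_config(n_samples = 10, n_probes = 4,
                                       n_informative = 2, seed = 6))
  ref <- cohort$expression
  qr <- ref[, c("sample_id", rev(setdiff(names(ref), "sample_id")))]
  expect_error(predict_nodal_risk(qr, ref, cohort$labels),
               class = "noderisk_probe_order_error")
})

test_that("leave-one-out predictions ignore the query's own label", {
  cohort <- simulate_cohort(sim_config(n_samples = 30, seed = 8))
  labels2 <- cohort$labels
  labels2$node_status[1] <- 1L - labels2$node_status[1]
  p1 <- predict_nodal_risk(cohort$expression, cohort$expression,
                           cohort$labels, leave_one_out = TRUE)
  p2 <- predict_nodal_risk(cohort$expression, cohort$expression, labels2,
                           leave_one_out = TRUE)
  expect_equal(p1$p[1], p2$p[1])
  # the flipped label does change predictions for samples positively
  # correlated with sample 1
  expect_false(isTRUE(all.equal(p1$p[-1], p2$p[-1])))
})

test_that("posterior probabilities obey the convexity, invariance and limit properties", {
  cohort <- simulate_cohort(sim_config(n_samples = 60, seed = 12))
  ref <- cohort$expression
  y <- cohort$labels
  pred <- predict_nodal_risk(ref, ref, y, leave_one_out = TRUE)
  expect_true(all(pred$p >= 0 & pred$p <= 1))

  # scale invariance under a strictly increasing transform of the query
  q <- ref[5, ]
  probes <- setdiff(names(q), "sample_id")
  qt <- q
  qt[probes] <- purrr::map(q[probes], ~ exp(0.5 * .x) + 3)
  expect_equal(predict_nodal_risk(qt, ref, y)$p,
               predict_nodal_risk(q, ref, y)$p)

  # monotonicity: flipping a positively weighted reference 0 -> 1 cannot
  # decrease p
  res <- posterior_risk(as.numeric(q[, probes]), ref, y, detail = TRUE)
  nb <- attr(res, "neighbors")
  idx <- which(nb$weight > 0 &
                 y$node_status[match(nb$sample_id, y$sample_id)] == 0)[1]
  y2 <- y
  y2$node_status[y2$sample_id == nb$sample_id[idx]] <- 1L
  expect_gte(posterior_risk(as.numeric(q[, probes]), ref, y2)$p, res$p)

  # prior dominance: s -> Inf pulls every posterior to pi0
  big <- predict_nodal_risk(ref, ref, y, prior_strength = 1e9,
                            baseline_prevalence = 0.23)
  expect_true(all(abs(big$p - 0.23) < 1e-6))
})

test_that("the k-nearest cut keeps ties deterministically", {
  # three references tied at rho = 1, one anti-correlated
  reference <- expr_tbl(rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(0, 1, 2, 3),
                              c(4, 3, 2, 1)),
                        sample_ids = sprintf("r%d", 1:4),
                        probe_ids = sprintf("P%d", 1:4))
  y <- c(1, 0, 1, 1)
  res <- posterior_risk(c(1, 2, 3, 4), reference, y, k = 1,
                        prior_strength = 0, detail = TRUE)
  nb <- attr(res, "neighbors")
  expect_equal(nb$used, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$p, 2 / 3)
})

test_that("a strongly informative synthetic cohort is recovered above chance", {
  cohort <- simulate_cohort(sim_config(n_samples = 200, effect_size = 2,
                                       seed = 33))
  pred <- predict_nodal_risk(cohort$expression, cohort$expression,
                             cohort$labels, leave_one_out = TRUE)
  auc <- roc_auc(pred$p, cohort$labels$node_status)
  n1 <- sum(cohort$labels$node_status == 1)
  n0 <- sum(cohort$labels$node_status == 0)
  se_null <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_gt(auc, 0.5 + 3 * se_null)
})
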