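#' Simulation configuration for synthetic expression cohorts
#'
#' Bundles and validates the parameters of the synthetic-data generators.
#' Defaults describe a cohort like the one the classifier targets: 21 probes
#' on a log2 intensity scale (probe baseline means drawn from
#' `N(baseline_mean, probe_mean_sd)`), a 23% prevalence of nodal
#' involvement, and node-positive tumours shifted by `effect_size` on the
#' informative subset of probes. Because the risk score uses rank
#' correlation, which ignores any shift common to all probes, a signal is
#' only detectable when the informative probes are a proper subset.
#'
#' @param n_samples Number of samples for [simulate_cohort()].
#' @param prevalence Probability a sample is node-positive (default 0.23).
#' @param n_probes Panel size (default 21).
#' @param n_informative Number of probes shifted in node-positive samples
#'   (default 10; must be `<= n_probes`).
#' @param effect_size Mean log-expression shift of informative probes in
#'   node-positive samples, in the same units as `noise_sd` (default 1).
#' @param within_class_correlation Equicorrelation of the noise across
#'   probes within a sample, in `[0, 1)` (default 0.1).
#' @param noise_sd Standard deviation of the log-scale noise (default 1).
#' @param pair_concordance Population correlation of matched FFPE/FF values
#'   per probe, in `[-1, 1]` (default 0.8).
#' @param specimen_shift Mean offset of cystectomy vs TUR specimens on the
#'   informative probes (default 0).
#' @param baseline_mean,probe_mean_sd Mean and SD of the per-probe baseline
#'   log2 intensities. The default SD of 0 gives the pure equicorrelated
#'   noise model; a positive SD adds probe-specific baselines, which makes
#'   all profile pairs rank-correlated and is only useful for stress
#'   testing.
#' @param seed Master seed; every generator derives its own deterministic
#'   stream from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500, prevalence = 0.23, n_probes = 21,
                       n_informative = 10, effect_size = 1,
                       within_class_correlation = 0.1, noise_sd = 1,
                       pair_concordance = 0.8, specimen_shift = 0,
                       baseline_mean = 7, probe_mean_sd = 0, seed = 1L) {
  cfg <- list(n_samples = n_samples, prevalence = prevalence,
              n_probes = n_probes, n_informative = n_informative,
              effect_size = effect_size,
              within_class_correlation = within_class_correlation,
              noise_sd = noise_sd, pair_concordance = pair_concordance,
              specimen_shift = specimen_shift, baseline_mean = baseline_mean,
              probe_mean_sd = probe_mean_sd, seed = seed)
  check_field <- function(ok, field) {
    if (!isTRUE(ok)) {
      stop_input(sprintf("Invalid simulation config field `%s`.", field),
                 "noderisk_config_error")
    }
  }
  check_field(is_count(n_samples, 1), "n_samples")
  check_field(is.numeric(prevalence) && prevalence > 0 && prevalence < 1,
              "prevalence")
  check_field(is_count(n_probes, 1), "n_probes")
  check_field(is_count(n_informative, 0) && n_informative <= n_probes,
              "n_informative")
  check_field(is.numeric(effect_size) && is.finite(effect_size),
              "effect_size")
  check_field(is.numeric(within_class_correlation) &&
                within_class_correlation >= 0 &&
                within_class_correlation < 1, "within_class_correlation")
  check_field(is.numeric(noise_sd) && noise_sd > 0, "noise_sd")
  check_field(is.numeric(pair_concordance) && pair_concordance >= -1 &&
                pair_concordance <= 1, "pair_concordance")
  check_field(is.numeric(specimen_shift) && is.finite(specimen_shift),
              "specimen_shift")
  check_field(is.numeric(probe_mean_sd) && probe_mean_sd >= 0,
              "probe_mean_sd")
  check_field(is_count(seed, 0), "seed")
  structure(cfg, class = "sim_config")
}

is_count <- function(x, min) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == as.integer(x) &&
    x >= min
}

# Run `expr` under a seed derived deterministically from the master seed and
# a per-generator stream offset, restoring the caller's RNG state afterwards.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((seed %% 715827882L) * 3L + stream)
  force(expr)
}

probe_names <- function(n) sprintf("P%03d", seq_len(n))

probe_baselines <- function(cfg) {
  # probe-specific baseline intensities, fixed per master seed so that
  # cohorts, matched pairs and specimen sets share a panel
  with_stream(cfg$seed, 0L,
              rnorm(cfg$n_probes, cfg$baseline_mean, cfg$probe_mean_sd))
}

informative_probes <- function(cfg) {
  probe_names(cfg$n_probes)[seq_len(cfg$n_informative)]
}

# n x p equicorrelated Gaussian noise: one shared standard normal per sample
# plus independent per-probe noise, mixed to correlation `rho`.
equicorr_noise <- function(n, p, rho, sd) {
  shared <- rnorm(n)
  eps <- matrix(rnorm(n * p), n, p)
  sd * (sqrt(rho) * shared + sqrt(1 - rho) * eps)
}

#' Simulate a labelled two-class expression cohort
#'
#' Draws nodal labels at the configured prevalence and generates log-scale
#' expression as probe baselines plus an `effect_size` shift on the
#' informative probes in node-positive samples plus equicorrelated Gaussian
#' noise. Fully reproducible from the config's seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expression` (samples x probes tibble),
#'   `labels` (tibble `sample_id`, `node_status`) and `informative_probes`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 20, seed = 7))
#' cohort$expression
simulate_cohort <- function(config) {
  cfg <- as_sim_config(config)
  m <- probe_baselines(cfg)
  with_stream(cfg$seed, 1L, {
    n <- cfg$n_samples
    y <- rbinom(n, 1L, cfg$prevalence)
    x <- matrix(m, n, cfg$n_probes, byrow = TRUE) +
      equicorr_noise(n, cfg$n_probes, cfg$within_class_correlation,
                     cfg$noise_sd)
    if (cfg$n_informative > 0) {
      x[, seq_len(cfg$n_informative)] <-
        x[, seq_len(cfg$n_informative)] + cfg$effect_size * y
    }
    ids <- sprintf("S%04d", seq_len(n))
    expr <- as_expression_tibble(x, ids, probe_names(cfg$n_probes))
    list(expression = expr,
         labels = tibble(sample_id = ids, node_status = as.integer(y)),
         informative_probes = informative_probes(cfg))
  })
}

#' Simulate matched FFPE/fresh-frozen sample pairs
#'
#' Generates paired preparations of the same tumours as a shared latent
#' signal plus independent preservation noise, mixed so that each probe's
#' FFPE and FF values have population correlation `pair_concordance` across
#' pairs. Sample IDs match across the two matrices; `preservation` metadata
#' is set.
#'
#' @param config A [sim_config()]; `pair_concordance` controls the
#'   within-pair correlation.
#' @param n_pairs Number of matched pairs (default 32).
#' @return A list with elements `ffpe` and `ff`, expression tibbles with
#'   identical `sample_id` sets.
#' @export
simulate_matched_pairs <- function(config, n_pairs = 32) {
  cfg <- as_sim_config(config)
  if (!is_count(n_pairs, 3)) {
    stop_input("Invalid simulation config field `n_pairs`.",
               "noderisk_config_error")
  }
  m <- probe_baselines(cfg)
  rho <- cfg$pair_concordance
  with_stream(cfg$seed, 2L, {
    p <- cfg$n_probes
    latent <- matrix(rnorm(n_pairs * p), n_pairs, p)
    e1 <- matrix(rnorm(n_pairs * p), n_pairs, p)
    e2 <- matrix(rnorm(n_pairs * p), n_pairs, p)
    a <- sqrt(abs(rho))
    b <- sqrt(1 - abs(rho))
    base <- matrix(m, n_pairs, p, byrow = TRUE)
    ffpe <- base + cfg$noise_sd * (a * latent + b * e1)
    ff <- base + cfg$noise_sd * (sign_or_one(rho) * a * latent + b * e2)
    ids <- sprintf("PAIR%03d", seq_len(n_pairs))
    list(
      ffpe = add_meta(as_expression_tibble(ffpe, ids, probe_names(p)),
                      preservation = "FFPE"),
      ff = add_meta(as_expression_tibble(ff, ids, probe_names(p)),
                    preservation = "FF"))
  })
}

sign_or_one <- function(x) if (x < 0) -1 else 1

#' Simulate independent TUR and cystectomy specimen sets
#'
#' Generates two independent groups of samples; the cystectomy group is
#' offset by `specimen_shift` on the informative probes. Group sizes default
#' to the design the fidelity screen targets (30 TUR vs 25 cystectomy).
#'
#' @param config A [sim_config()]; `specimen_shift` controls the offset.
#' @param n_tur,n_cyst Group sizes, each `>= 2`.
#' @return A list with elements `tur` and `cyst`, expression tibbles with
#'   `specimen_source` metadata.
#' @export
simulate_specimen_sets <- function(config, n_tur = 30, n_cyst = 25) {
  cfg <- as_sim_config(config)
  if (!is_count(n_tur, 2) || !is_count(n_cyst, 2)) {
    stop_input("Invalid simulation config field `n_tur`/`n_cyst`.",
               "noderisk_config_error")
  }
  m <- probe_baselines(cfg)
  with_stream(cfg$seed, 3L, {
    p <- cfg$n_probes
    tur <- matrix(m, n_tur, p, byrow = TRUE) +
      cfg$noise_sd * matrix(rnorm(n_tur * p), n_tur, p)
    shift <- rep(0, p)
    if (cfg$n_informative > 0) {
      shift[seq_len(cfg$n_informative)] <- cfg$specimen_shift
    }
    cyst <- matrix(m + shift, n_cyst, p, byrow = TRUE) +
      cfg$noise_sd * matrix(rnorm(n_cyst * p), n_cyst, p)
    list(
      tur = add_meta(as_expression_tibble(
        tur, sprintf("TUR%03d", seq_len(n_tur)), probe_names(p)),
        specimen_source = "TUR"),
      cyst = add_meta(as_expression_tibble(
        cyst, sprintf("CYS%03d", seq_len(n_cyst)), probe_names(p)),
        specimen_source = "cystectomy"))
  })
}

as_sim_config <- function(config) {
  if (inherits(config, "sim_config")) return(config)
  if (is.list(config)) return(do.call(sim_config, config))
  stop_input("`config` must be a sim_config() or a named list of its fields.",
             "noderisk_config_error")
}

as_expression_tibble <- function(x, sample_ids, probe_ids) {
  out <- as_tibble(x, .name_repair = "minimal")
  names(out) <- probe_ids
  dplyr::bind_cols(tibble(sample_id = sample_ids), out)
}

add_meta <- function(x, preservation = NULL, specimen_source = NULL) {
  if (!is.null(preservation)) x$preservation <- preservation
  if (!is.null(specimen_source)) x$specimen_source <- specimen_source
  # keep metadata columns right after sample_id
  x[, c("sample_id", intersect(.meta_cols, names(x)),
        setdiff(names(x), c("sample_id", .meta_cols)))]
}
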