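Package: noderisk
Title: Gene-Expression Prediction of Occult Nodal Involvement in
    Muscle-Invasive Bladder Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a 20-gene (21-probe) expression classifier of occult
    lymph-node involvement for muscle-invasive bladder cancer: high-fidelity
    probe screening across matched FFPE/fresh-frozen pairs and specimen
    sources, a Spearman-correlation-weighted Bayesian nearest-neighbor
    posterior risk score stratified into low/intermediate/high risk against a
    23% baseline prevalence, and a clinical-performance evaluator with
    prevalence-adjusted predictive values, per-group relative risks and ROC
    AUC. Includes seeded synthetic-cohort generators so every component is
    testable without external data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
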