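Package: pgxscreen
Title: Pharmacogenomic Biomarker Discovery from Cell-Line Drug Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering expression biomarkers of
    drug sensitivity in cell-line pharmacological screens. Quantifies
    multi-dose viability curves as normalized area-under-curve (AUC) values,
    preprocesses FPKM expression matrices (log2, quantile normalization,
    per-gene Z-scores), fits elastic-net regression of drug response on
    expression by cyclic coordinate descent with cross-validated penalty
    selection, and calls biomarkers by bootstrap stability selection
    (selection frequency and average weight thresholds). Also provides
    mutation-stratified association tests (exact Wilcoxon rank-sum and
    two-sample Kolmogorov-Smirnov) and a seeded synthetic-screen generator
    with planted gene-drug effects for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
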