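Package: fallrisk
Title: Fall-Risk Classification from Ground Reaction Force Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for assessing fall risk in older adults from ground
    reaction force (GRF) recordings. Walking and sit-to-stand force
    signals are quantified by sample entropy, classified with three
    nearest-neighbour variants (local mean k-NN, pseudo nearest
    neighbour, and local mean pseudo nearest neighbour) under exhaustive
    feature-subset selection with leave-one-out cross-validation, and
    compared between fallers and non-fallers with Wilcoxon rank-sum
    tests and Spearman correlations. Includes a calibrated synthetic
    cohort generator for fully reproducible end-to-end analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
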