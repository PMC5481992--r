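Package: eriselect
Title: Early Response Index Feature Selection for Early-Stage Biomarker
    Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Prioritizes candidate biomarkers in two-class omics data by the
    Early Response Index (ERI): each feature is scored by the average
    cross-validated classification-accuracy improvement it contributes when
    paired with every other feature, so weakly but consistently shifted
    "early responder" features rank highly even when their marginal
    differential expression is unremarkable. Includes a label-permutation
    scheme that sets a zero-false-positive-rate significance cutoff, a
    peptide-to-protein preprocessing chain for isobaric (TMT-style)
    reporter-channel quantification (duplicate-peptide merging,
    reference-channel ratios, quantile normalization, median rollup,
    missing-value filtering and imputation), and a synthetic-data generator
    for validating every stage. The pairwise support-vector-machine
    cross-validation workload is evaluated by a compiled sequential
    minimal optimization solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    limma,
    parallel,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
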