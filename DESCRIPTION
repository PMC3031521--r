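Package: mitoevidence
Title: Integrative Prediction of Nucleus-Encoded Mitochondrial Proteins and
    Network-Based Function Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates heterogeneous genome-scale binary predictors of
    mitochondrial localization with a naive Bayes likelihood-ratio model,
    including an N50 coexpression-neighbour predictor trained with a decision
    tree. Provides confusion-matrix metrics, ROC curves with threshold
    selection, and stratified k-fold cross-validation for the integrated
    classifier; infers protein function from protein-interaction-network
    neighbourhoods via Czekanowski-Dice and transitive similarity (FunScore)
    with permutation-based empirical p-values; and tests functional enrichment
    of stress-induced interaction subnetworks with hypergeometric tests and
    Benjamini-Hochberg correction. Ships a synthetic-data module that emulates
    the statistical structure these methods assume, so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
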