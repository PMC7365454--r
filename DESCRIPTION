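Package: sarcomiR
Title: Serum miRNA-Pair Classifier for Sarcoma Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rank-comparison miRNA-pair features for circulating biomarker
    classification. Builds binary gene-pair indicators from log2 serum miRNA
    expression (which of two miRNAs is higher within a sample), screens genes
    and pairs with two-sample t tests, and classifies samples with a bagged
    forward-selected logistic ensemble (random generalized linear model) with
    out-of-bag accuracy estimation and occurrence-based thinning. Includes
    K-nearest-neighbour expression imputation, abundance filtering, stratified
    train/test splitting, confusion-matrix metrics, and a synthetic-cohort
    generator with planted rank-flipping pairs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
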