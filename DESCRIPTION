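Package: eplearn
Title: Supervised Learning of Enhancer-Promoter Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for predicting functional enhancer-promoter
    (EP) pairs from perturbation screens integrated with chromatin assays.
    Implements candidate-pair enumeration within a genomic window,
    activity-by-contact (ABC) scoring, relative-contact and element-density
    feature engineering, promoter-centric chromatin interaction network
    (ChIN) graph-distance labeling, genomically blocked nested
    cross-validation, non-negative matrix factorization of transcription
    factor co-binding, gradient-boosted classification with shadow-feature
    (Boruta-style) selection and Shapley attribution, and imbalance-aware
    evaluation. A synthetic-data generator emulating the statistical
    structure of genome-wide CRISPRi enhancer screens makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    xgboost,
    GenomicRanges,
    IRanges,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
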