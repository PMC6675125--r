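Package: mdforest
Title: Ensemble of Regression Trees for miRNA-Disease Association Prediction
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a binary
    association matrix, a precomputed miRNA functional similarity matrix and
    a disease term ontology. Disease similarity combines two DAG-based
    semantic models with a Gaussian interaction-profile kernel fallback;
    per-entity feature vectors (statistical, graph-theoretic and matrix
    factorization blocks) feed an ensemble of CART regression trees, each
    base learner trained on freshly resampled negatives, a random feature
    subset and per-side principal component projections. Includes global and
    local leave-one-out cross validation, repeated k-fold cross validation
    with per-fold similarity recomputation, a label-randomization control,
    a bagging (random-forest style) baseline, and a synthetic block-model
    data generator so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
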