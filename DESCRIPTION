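Package: carenet
Title: Hierarchical Attention Networks for Diagnosis from Health-System Event Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies emergency-department dyspnoea visits into acute heart
    failure, exacerbated COPD, pneumonia and other diagnoses from time-stamped,
    context-grouped electronic health record event streams. Implements the
    CareNet architecture: a three-layer hierarchy of bidirectional GRU encoders
    with attention pooling over events, care contexts and time periods,
    skip-gram pretraining of event-code embeddings, an evidential (Beta)
    multilabel output head, the matching cross-validation/bootstrap evaluation
    protocol with micro-averaged AUROC and sensitivity at a specificity floor,
    attention-product variable importance, an expert-feature gradient-boosted
    baseline with iterative random-forest imputation, and a synthetic EHR
    cohort generator with planted diagnostic signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    ranger,
    xgboost,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
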