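Package: faceerp
Title: Individual-Level Analysis of Infant Face-Processing ERPs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for event-related-potential (ERP) studies of
    infant face processing in cohorts at elevated likelihood of autism. Extracts
    P1/N290/P400 peak amplitude and latency features from epoched waveforms,
    imputes missing features by expectation-maximization under a multivariate
    Gaussian model, runs split-plot (condition-by-group) ANOVAs with post-hoc
    effect sizes, selects predictive feature sets with a genetic algorithm
    wrapped around a cross-validated linear support-vector-machine classifier
    (with permutation and bootstrap inference), predicts continuous social-trait
    outcomes with elastic-net regression under nested cross-validation, and
    stratifies subjects into subgroups with Bayesian hierarchical clustering
    under a Dirichlet-process prior. Includes a synthetic cohort generator that
    plants known effect structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    e1071,
    mclust,
    lmtest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite
Config/testthat/edition: 3
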