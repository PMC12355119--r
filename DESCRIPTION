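Package: symptomnet
Title: Symptom Network Analysis for Ordinal Questionnaire Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and comparison of psychological symptom networks from
    ordinal questionnaire data. Provides instrument scoring and reliability,
    polychoric correlation estimation, redundancy screening by topological
    overlap, regularized Gaussian graphical models selected with the extended
    Bayesian information criterion, node and bridge centrality, bootstrap
    accuracy and case-dropping stability analysis, permutation-based network
    comparison between groups, score-based Bayesian network structure learning
    with bootstrap model averaging, and Ising-model computer-simulated
    interventions that rank symptoms as intervention targets. A synthetic
    ordinal-data generator with known sparse latent network structure supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
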