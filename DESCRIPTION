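Package: symptomnet
Title: Regularized Partial Correlation Networks for Clinical Symptom,
    Cognition and Social Function Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates Gaussian graphical models over clinical rating-scale
    items with the graphical lasso (block coordinate descent, extended-BIC
    penalty selection) and converts them to regularized partial-correlation
    networks. Computes node centrality (strength, expected influence,
    closeness, betweenness) and bridge strength across declared clinical
    domains, and quantifies estimation uncertainty with nonparametric
    edge-weight bootstraps and case-dropping correlation-stability (CS)
    coefficients. Ships a synthetic two-group data generator with
    block-structured ground-truth partial correlations emulating negative
    symptom items, cognitive domain scores and a social-function total, plus
    Welch two-sample group comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
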