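Package: fearleak
Title: Leaked-Fear Facial Action Unit Analysis for High-Stakes Deception
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing leaked fear in facial action-unit (AU) time
    series extracted with OpenFace-style landmark/AU trackers. Implements
    per-frame fear-AU scoring (presence times intensity), segmentation of AU
    activations into onset/apex/offset episodes with micro/macro-expression
    duration thresholds, a wavelet-coherence facial-asymmetry metric on
    left/right eyebrow-eye distance signals, bootstrap and permutation
    inference with Bonferroni correction, and an imbalanced-classification
    stage (SMOTE oversampling; random forest, k-nearest-neighbour and bagging
    learners) with participant-aware evaluation. A synthetic cohort generator
    emulates the statistical structure of game-show deception clips so the
    whole pipeline is testable without restricted video data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    FNN,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
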