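Package: fexdyn
Title: Spatiotemporal Decomposition and Kinematic Substate Analysis of
    Facial Action Unit Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for analysing emotional facial movement
    dynamics from OpenFace-dialect action unit (AU) intensity timeseries.
    Decomposes stacked AU trials into low-dimensional spatiotemporal
    components by non-negative matrix factorization with consensus-based
    rank selection against a block-shuffled null, quantifies the diagnostic
    value of component dynamics for emotion classification via an
    interpretable timeseries-feature catalog, PCA summarisation and a
    random-forest classifier with exact and permutation significance tests,
    and segments trials into kinematic substates (relaxed, sustain,
    transition) by dynamic-time-warping clustering of speed and
    displacement, summarised by substate speed and normalised transition
    entropy and characterised with linear mixed-effects models. Includes a
    synthetic AU-trial generator with planted low-rank structure and
    substate schedules for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    Matrix,
    pracma,
    randomForest,
    e1071,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
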