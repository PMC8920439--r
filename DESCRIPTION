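Package: phenotrack
Title: Video Tracking, Behavioral Phenotyping, Lifespan Modelling and
    Phenotypic-Age Clocks for Small Aquatic Animals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for automated phenotyping of small
    swimming animals such as Daphnia magna. Detects and tracks many
    animals in grayscale video via background subtraction, blob
    segmentation and frame-to-frame identity linking; extracts
    natural-swimming, morphological, locomotor-state (ethogram) and
    stimulus-response features; builds Kaplan-Meier lifespan curves with
    log-rank comparison and seven-family parametric survival fits; and
    trains cross-validated phenotypic-age regressors with
    imbalanced-regression oversampling, permutation feature importance
    and origin-forced aging-rate slopes. A ground-truthed synthetic
    cohort and video generator makes every stage testable without a
    physical imaging rig.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    zoo,
    withr,
    survival,
    flexsurv,
    glmnet,
    ranger,
    xgboost,
    e1071,
    EBImage,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
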