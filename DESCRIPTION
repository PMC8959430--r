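Package: kdemg
Title: Kernel Density Features and Ensemble Learning for Surface EMG
    Movement Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature extraction, feature selection, and ensemble
    classification for multi-channel surface electromyographic (sEMG)
    recordings, centred on three kernel-density-estimation features per
    channel: the trimmed mean of the density (TMD), the approximate
    entropy of the density (ED), and the trimmed mean absolute value of
    the density derivative (TMAVDD). Includes a diffusion-bandwidth
    kernel density estimator, Hermite-polynomial density derivatives,
    correlation-based feature selection with best-first search,
    LDA/SVM/MLP base learners fused by Behavioral Knowledge Space,
    gradient-boosted trees for simultaneous two-movement classification,
    evaluation metrics and split schemes, and a seeded synthetic sEMG
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    nnet,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
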