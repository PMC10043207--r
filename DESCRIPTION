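Package: afablate
Title: In Silico Atrial Fibrillation Ablation Strategies and Interpretable
    Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.com>
Description: Generates synthetic two-dimensional left-atrial tissue disks
    with pulmonary-vein openings and patchy fibrosis, simulates atrial
    fibrillation and its termination by three catheter-ablation strategies
    (pulmonary-vein isolation, fibrosis-border ablation and rotor-core
    ablation) with a three-variable Fenton-Karma monodomain model, trains
    a multi-label convolutional neural network to predict each strategy's
    success from the tissue image alone, and quantifies how well gradient,
    perturbation and surrogate feature-attribution maps (GradCAM,
    occlusions, LIME) localise the hidden ablation lesions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
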