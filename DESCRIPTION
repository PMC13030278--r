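Package: strokemark
Title: Stroke Lesion Imaging Biomarkers from ADC Maps and Segmentation Masks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated extraction of quantitative imaging biomarkers for
    ischemic stroke downstream of deep-learning lesion segmentation.
    Fuses candidate lesion masks by voxel-wise majority voting, computes
    19 named volumetric, spatial, intensity, grey-level co-occurrence
    texture, and corticospinal-tract overlap features from apparent
    diffusion coefficient (ADC) volumes and binary masks in NIfTI format,
    and runs an exploratory modified Rankin Scale outcome-modelling
    protocol (ANOVA feature selection, stratified split, cross-validated
    tree ensembles, bootstrap confidence intervals, permutation feature
    importance). Includes a seeded synthetic phantom generator so every
    stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    Rcpp,
    randomForest,
    pROC,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
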