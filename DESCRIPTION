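Package: planqa
Title: Dosimetric and Geometric Quality Assurance for Radiotherapy Trial Plans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quality-assurance toolkit for multi-center radiotherapy treatment
    plans on a shared voxel grid: cumulative dose-volume histograms and the
    standard plan metrics (D98/D50/D2, dose to the hottest 0.03 cc, Dmean,
    V40/V45), equivalent-uniform-dose (EUD) based logistic NTCP modelling of
    brain radionecrosis risk with ratio and logarithmic increased-risk
    statistics, volumetric contour-similarity metrics (Dice, Hausdorff and
    95th-percentile Hausdorff distance), and config-driven protocol-compliance
    scorecards. Includes a seeded synthetic head-phantom generator (nested
    target volumes, PET-like uptake with threshold segmentation, dual 60/75 Gy
    simultaneous-integrated-boost dose models, stochastic contour perturbation)
    so the full pipeline is exercisable without patient data, plus a bundle
    format (NIfTI volumes + JSON manifest) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
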