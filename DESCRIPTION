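Package: hemoflow
Title: Quantitative Conjunctival Microcirculation Video Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantitative analysis of conjunctival
    microcirculation slit-lamp videos: sharpest-frame selection and rigid
    frame registration, multiscale Hessian vessel enhancement,
    skeletonization and segment decomposition, Euclidean distance transform
    diameter estimation, spatio-temporal image (STI) velocimetry with
    continuous wavelet transform filtering, conversion of diameter and
    axial velocity to cross-sectional velocity, blood volume flow and wall
    shear rate, diameter-group classification, two-cohort and per-group
    statistics with normality gating, and test-retest repeatability
    coefficients. Includes a ground-truthed synthetic vessel-video and
    cohort generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    car,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
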