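Package: thermoroi
Title: Thermal Imaging Analysis of Induced Skin Cooling with Elliptical
    Regions of Interest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying induced skin cooling from paired
    optical and thermal images: cross-device melanin-index calibration and
    skin-tone classification, affine optical-to-thermal registration from
    fiducial point correspondences, direct least-squares elliptical
    region-of-interest fitting with an automatically placed control region,
    median-temperature extraction, and linear mixed-effects models for
    camera, environment, and skin-tone effects on measured temperature
    change. Includes a synthetic-data generator that emulates the full
    repeated-measures imaging design with known ground truth, so every
    stage can be exercised and validated without access to raw clinical
    images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
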