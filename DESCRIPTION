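Package: bloodhsi
Title: Discrimination of Human and Animal Bloodstains from Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for visible-near-infrared hyperspectral
    imaging (HSI) of bloodstains: reflectance calibration of raw hypercubes
    against dark and white references, ENVI-style persistence, spectral
    preprocessing (band truncation, Savitzky-Golay smoothing, standard normal
    variate), age-binned hierarchical undersampling of pixel spectra,
    neighbourhood component feature selection (NCFS) of discriminative
    wavelengths, spectral background detection for bloodstain masking, and
    pixel-wise polynomial-kernel SVM classification of human versus animal
    blood with per-image segmentation overlays. Includes a synthetic
    bloodstain-scene generator built on Gaussian-peak haemoglobin-derivative
    absorbance templates with exponential ageing kinetics, so the full pipeline
    is reproducible and testable without access to laboratory HSI cubes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    grDevices,
    signal,
    e1071,
    class,
    EBImage,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    broom,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
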