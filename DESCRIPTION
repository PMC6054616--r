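Package: fluorostage
Title: Autofluorescence Spectroscopy Pipeline for Liver Fibrosis Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of 410 nm-excited liver autofluorescence
    emission spectra (440-750 nm) for staging hepatic fibrosis. Provides a
    seeded forward simulator of group-labelled spectra (overlapping NADH, FAD,
    lipopigment and porphyrin Gaussian emission bands attenuated by
    Beer-Lambert hemoglobin absorption with an isosbestic construction at 500
    and 570 nm), peak-window normalization, multi-Gaussian band decomposition
    by bounded Levenberg-Marquardt least squares, a ratiometric
    spectral-filtering-modulation index of total hemoglobin, pairwise PCA-LDA
    classification with ROC/AUC and confusion-ellipse reporting, and one-way
    ANOVA group statistics. All results are returned as tibbles and the whole
    pipeline is reproducible from a single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
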