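Package: boutonkit
Title: Quantitative Analysis of pHluorin Synaptic Vesicle Recycling Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying synaptic vesicle exo- and endocytosis from
    pHluorin (sypHy) time-lapse fluorescence microscopy and for morphometry of
    synaptic boutons in fixed-tissue images. Implements iterative-threshold
    synaptic puncta detection with area and roundness filtering, dF/F0 trace
    normalization, single-exponential endocytosis kinetics with a time-constant
    discard rule, recycling-pool sizing from bafilomycin experiments, Gaussian
    line-profile FWHM dispersion analysis, two-channel synaptic enrichment
    scoring, and a normality-gated statistical comparison procedure with Grubbs
    outlier screening. A seeded synthetic-data generator emulates traces, bouton
    image fields, time-lapse stacks and two-channel line profiles with known
    ground truth so that every stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
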