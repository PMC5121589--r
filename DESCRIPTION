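Package: alphaspec
Title: Source-Space Alpha-Band Spectral Analysis for Cognitive Decline Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for resting-state MEG/EEG
    alpha-band studies of cognitive decline. Generates synthetic three-group
    cohorts (controls, subjective cognitive decline, mild cognitive
    impairment) with subject-specific alpha oscillations over 1/f background
    noise; reconstructs source activity with an LCMV beamformer over a
    regular source grid; estimates relative power spectra with DPSS
    multitaper; anchors the alpha band to the individual alpha frequency
    (IAF); fits each source spectrum to a Gaussian peak over a power-law
    background to extract the alpha peak frequency; and performs group
    inference with age-adjusted ANCOVA, cluster-based permutation tests with
    a Freedman-Lane covariate scheme, and an FDR-corrected two-predictor
    regression battery linking spectral parameters to cognition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
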