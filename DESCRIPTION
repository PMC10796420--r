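Package: plaquemra
Title: Quantification of Iron-Particle-Enhanced Carotid MR Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative analysis pipeline for dual-targeted
    microparticle-of-iron-oxide (MPIO) enhanced time-of-flight MR
    angiography of the mouse carotid artery. Implements paired
    pre-/post-contrast volume registration, control-artery threshold
    selection, lumen binarization and connected-component delineation,
    per-slice lumen-area curves, landmark-based partitioning of the
    cuffed carotid into shear-stress regions (R1-R5), and the per-region
    area-under-curve difference statistic that measures bound-particle
    hypointensity. Also provides the histological plaque vulnerability
    index, rule-based AHA lesion typing, group and region statistical
    comparisons, and a synthetic phantom and cohort generator that
    emulates the cuff-implanted atherosclerosis study design so the
    whole pipeline is testable end-to-end without animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    tiff,
    yaml,
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
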