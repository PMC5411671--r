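Package: tpm3d
Title: 3-D Reconstruction and Hotspot Concordance for Transperineal Template
    Mapping Biopsy Pathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rebuilds three-dimensional prostate cancer lesions from core-level
    transperineal template mapping (TPM) biopsy pathology reported on a 5 mm
    brachytherapy grid, delineates independent lesions by 26-connectivity on the
    13x13x40 coarse map, reconstructs a 0.5 mm isotropic grade map by trilinear
    interpolation and grid-site-preserving Gaussian smoothing, and simulates
    cranio-caudal virtual biopsy needles to locate each lesion's volume hotspot
    (longest cancer core length) and Gleason grade hotspot. Quantifies hotspot
    concordance under four definitional configurations (separate vs cumulative
    cancer core length counting, Gleason-grades vs Gleason-score heterogeneity)
    with Wald binomial confidence intervals, and ships a synthetic cohort
    generator with planted ground-truth lesions so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    RNifti,
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
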