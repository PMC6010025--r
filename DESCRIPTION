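Package: hifubreast
Title: Breast HIFU Focal-Error Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital breast phantoms, histogram-based tissue segmentation,
    heterogeneous-media finite-difference time-domain (FDTD) simulation of
    focused ultrasound, time-reversal focus control for a spherical-cap
    phased array, and focal-quality metrics (localized heating ratio,
    focusing ratio, local acoustic inhomogeneity) for studying how breast
    fibroglandular structure distorts the focus of high-intensity focused
    ultrasound (HIFU) therapy. Includes an axisymmetric Rayleigh-integral
    reference solution for free-field validation and an ensemble driver
    that relates focal quality to an impedance-gradient inhomogeneity
    indicator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
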