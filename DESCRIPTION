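Package: elastomap
Title: Time-Lapse AFM Elastography Maps, Stiffness-Gradient Kinetics and
    Companion Image Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-lapse in vivo atomic force microscopy
    (AFM) elastography of developing tissue. Converts raw force-distance
    curves to apparent elastic moduli by Hertz-model fitting with automated
    contact-point detection and quality control, smooths and imputes gridded
    spatiotemporal stiffness arrays by penalized least squares in the
    discrete cosine basis (with generalized cross-validation and a robust
    mode), computes region-of-interest stiffness gradients and fold-change
    maps, rescales gradient and axon turn-angle time series to extrapolate
    onset times and gradient-to-turning delays, and provides image-derived
    metrics (nuclear density fractions, moment-ellipse elongation, Sholl
    profiles, mitotic-cell densities, normalized brain areas). A synthetic
    scene generator simulates every input the pipeline consumes so all
    stages are testable without instrument data.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
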