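Package: sdpcv1
Title: Sparse Deep Predictive Coding Models of Primary Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-layer convolutional sparse coding network with hierarchical
    predictive-coding feedback and interchangeable max-pooling operators
    (spatial, circular 1D feature, toroidal 2D feature), used to study how the
    pooling strategy controls the joint emergence of phase-invariant (complex)
    cells and topographic orientation maps in models of primary visual cortex.
    Includes dictionary learning by ISTA-style inference and momentum gradient
    steps, natural-image whitening, a synthetic natural-like image generator,
    drifting and rotating grating protocols, and the analysis battery:
    modulation ratio (F1/F0), rectified-sine response fits and the chi index,
    log-Gabor receptive-field fitting, second-layer back-projection, local
    homogeneity index (LHI), pinwheel detection and density, and population
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png,
    withr
Config/testthat/edition: 3
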