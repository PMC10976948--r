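Package: hyperseed
Title: Hyperspectral Seed Maturity Classification Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end chemometrics pipeline for classifying seed maturity
    stages from visible/near-infrared hyperspectral images. Covers reflectance
    calibration of raw hypercubes against dark and white references, Otsu
    segmentation and connected-component seed extraction, spectral
    pretreatments (Savitzky-Golay smoothing, derivatives, standard normal
    variate, detrending), class-stratified Kennard-Stone sample partitioning,
    wavelength selection by the successive projections algorithm (SPA),
    competitive adaptive reweighted sampling (CARS), an iterative variable-
    space shrinkage interval selector and their SPA hybrids, and a five-way
    classifier comparison (extreme learning machine, k-nearest neighbours,
    random forest, PLS-DA, and a particle-swarm-tuned RBF support vector
    machine). A seeded synthetic-data generator emulates the spectral
    structure of a three-stage oilseed rape maturity study so every stage of
    the pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    ranger,
    jsonlite,
    data.table,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    mixOmics,
    withr
Config/testthat/edition: 3
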