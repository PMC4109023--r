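Package: thrombotype
Title: Multi-Surface Multi-Parameter Analysis of Thrombus Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for microspot flow-chamber assays of
    platelet thrombus formation. Converts phase-contrast and fluorescence
    microscopy into eight thrombus parameters (surface coverage, integrated
    feature size, morphological score, stable adhesion, marker coverages,
    thrombus volume), assembles multi-surface parameter matrices on a common
    0-10 scale, clusters surfaces into thrombus types I-III with
    multiscale-bootstrap (approximately unbiased) cluster support, fits
    partial least-squares models linking a binary platelet-receptor
    assignment matrix to thrombus type, and profiles patient samples against
    healthy reference ranges with mean +/- 2 s.d. significance maps. Ships a
    synthetic-data generator with known ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    Rcpp,
    jsonlite,
    tiff,
    ape,
    mclust,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
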