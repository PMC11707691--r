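Package: serialindex
Title: Still-Image Serial Crystallography Processing: Peak Search, FFT
    Autoindexing, Cell Checking and Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for processing still diffraction
    images from serial crystallography experiments. Implements Bragg-peak
    finding in the peakfinder8 style with precomputed annular background
    statistics and a fast subsampled variant, an FFT-based autoindexing
    algorithm that searches one-dimensional periodicities along triplet
    plane normals, reference-cell checking via Niggli reduction and G6
    comparison, reflection prediction and integration, hierarchical
    pipeline profiling, an in-memory run-stream with consumer-group
    semantics, and a synthetic still-pattern simulator with known
    ground-truth cells so that every stage is testable without detector
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
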