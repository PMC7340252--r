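Package: cryopick
Title: Self-Supervised Particle Picking for Cryo-EM Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating single particles on cryo-electron microscopy
    micrographs without manual labelling. Provides an ab initio shape-based
    picker built on adaptive local thresholding, reference-free 2D class
    averaging with Fourier-ring-correlation resolution estimates and the
    percent-distribution-over-resolution (%/Res) class-selection rule, a
    small convolutional neural network particle classifier trained
    iteratively from its own filtered picks, a workflow driver implementing
    the 90% selection and 70% convergence rules with a three-iteration cap,
    and a synthetic-micrograph test bench with ground-truth evaluation
    metrics. Reads and writes MRC2014 images and Relion-dialect STAR
    coordinate and class-metadata files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
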