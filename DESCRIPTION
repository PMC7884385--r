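Package: wormsnap
Title: Automated Scoring of C. elegans Swimming Postures from Well Snapshots
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Segment-train-quantify toolkit for high-throughput curling
    assays in Caenorhabditis elegans. Detects worm-shaped objects in
    single-well snapshot images by multilevel Otsu thresholding of the
    image gradient, standardizes them to 128x128 mask crops, trains a
    five-class convolutional neural network (Coiled, Curled, Near-curled,
    Non-curled, Censored) on labeled crops, and scores snapshots by
    ensemble-averaging network outputs over multiple binarizations and
    mask dilations per object. A cubic B-spline body model (tangent-angle
    and half-width profiles along the centerline) supports morphological
    analysis and drives a seeded synthetic-image generator, so every stage
    is trainable and testable without real image data. Downstream screen
    analytics cover per-well curling metrics, vehicle normalization, hit
    calling, time-decay fits, and group comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    multcomp,
    png,
    Rcpp,
    splines,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
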