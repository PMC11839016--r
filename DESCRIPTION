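Package: celldist
Title: Cell Instance Segmentation via Distance-Map Regression and
    Marker-Controlled Watershed
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments cells in label-free microscopy images by regressing a
    per-cell normalized Euclidean distance map and recovering instances with a
    marker-controlled watershed. Provides CLAHE-based preprocessing and
    zero-mean/unit-variance standardization, overlapping sliding-window tiling
    with exact single-ownership stitching, ground-truth distance-map encoding,
    training-time augmentation, a pluggable patch predictor (ground-truth
    oracle and a small trainable convolutional backbone with an AdamW
    trainer), dual-threshold watershed post-processing, Cell Tracking
    Challenge SEG and DET (AOGM-D) evaluation measures, per-image culture
    statistics (count, area, confluency, neighbors), and a deterministic
    synthetic culture generator for offline end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    tiff,
    Rcpp,
    yaml,
    tibble,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
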