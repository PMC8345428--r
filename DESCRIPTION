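Package: ptcscreen
Title: Fast Screening of Cytological Whole-Slide Images for Papillary
    Thyroid Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tile-based screening pipeline for papanicolaou-stained
    cytological whole-slide images. Decomposes pyramidal TIFF slides into a
    hierarchical tile grid, discards background tiles with a fast
    saturation-based tissue detector, segments the remaining tiles with a
    padded VGG16 fully convolutional network (FCN-32s style) trained by
    stochastic gradient descent, stitches per-tile class maps into a
    whole-slide papillary thyroid carcinoma mask, and evaluates segmentations
    with pixel-level metrics (accuracy, precision, recall, F1, Jaccard) and
    Fisher's least-significant-difference comparisons across methods. A
    deterministic synthetic slide generator provides ground-truthed
    papanicolaou-like fixtures so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    jsonlite,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
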