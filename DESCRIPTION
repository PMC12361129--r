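Package: axonfield
Title: Distance-Field Supervised Segmentation and Evaluation of Axonal Image Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing axonal centerlines from 3D fluorescence
    microscopy volumes with distance-field regression. Converts SWC skeleton
    annotations into Gaussian-decay distance-field supervision labels, trains a
    3D U-Net regressor with a region-weighted L1 loss, enhances raw volumes by
    overlaying scaled predictions, extracts and skeletonizes foreground point
    clouds, and scores reconstructions with skeleton-matching recall, precision,
    F1 and the Aggregated Jaccard Index. Includes a synthetic tubular phantom
    generator spanning realistic signal-to-noise ratios, per-sub-block volume
    characterization, and K-means grayscale-histogram block selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
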