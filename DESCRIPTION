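Package: scoutbox
Title: Automated Placement of Breast MRI Scan and Pre-Scan Volumes from Scout Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for automated graphical prescription in bilateral breast MRI:
    axis-aligned 3D box geometry with intersection-over-union (IoU) and 3D
    generalized IoU (GIoU) kernels, a synthetic prone-breast scout phantom
    generator with guideline-derived ground-truth volumes, maximum-intensity
    projection (MIP) plus Otsu preprocessing of 3-plane scout series, an
    AlexNet-style convolutional regressor for the 5-parameter scan volume and
    the 9-parameter bilateral pre-scan (local calibration) volume pair,
    cross-validated training with RMSE or GIoU losses, Monte-Carlo-dropout
    uncertainty estimation, and a cohort evaluation suite reporting 3D/2D IoU,
    center distance, volume error, overlap and parameter RMSE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    tools,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    withr
Config/testthat/edition: 3
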