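Package: dipmap
Title: Initial-Dip Functional t-Maps and CNN Classification for fNIRS Finger Tapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-channel oxyhemoglobin (dHbO) finger-tapping fNIRS
    sessions with a ground-truth activation footprint, models the hemodynamic
    response with a three-gamma canonical HRF that includes the initial dip,
    computes per-trial robust-regression (IRLS bisquare) t-statistics of dHbO
    against the designed regressor over initial-dip windows, renders thresholded
    and normalized topographic activation t-maps as images, and classifies two
    tapping tasks (right-hand thumb vs. little finger) with a configurable
    layered convolutional neural network trained by stochastic gradient descent
    with momentum. Includes confusion-matrix metrics (TPR, FNR, PPV, FDR),
    ROC/AUC, and an end-to-end reproducible experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    optparse
Config/testthat/edition: 3
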