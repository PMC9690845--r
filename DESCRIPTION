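Package: estan
Title: Enhanced Small Tumor-Aware Network for Breast Ultrasound Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds, trains and evaluates the Enhanced Small Tumor-Aware
    Network (ESTAN), a dual-encoder convolutional architecture for
    segmenting tumors in breast ultrasound (BUS) images. One encoder is a
    conventional two-convolution contracting path; the second applies
    large row-column-wise (1-D) kernels matched to the horizontally
    stacked breast tissue anatomy. The package includes the full
    evaluation protocol used for BUS segmentation benchmarks: seven
    area and boundary metrics with the BUS-specific false-positive-rate
    convention, tumor-size stratification by longest-axis length,
    k-fold cross-validation, and paired Wilcoxon signed-rank testing
    with Holm-Bonferroni correction. A synthetic layered-ultrasound
    phantom generator with speckle noise and controllable tumor size
    makes the whole pipeline testable without clinical data. The
    convolutional core (forward/backward passes and Adam optimisation)
    is implemented in C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    jsonlite,
    grDevices,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
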