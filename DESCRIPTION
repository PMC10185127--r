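Package: onquant
Title: Optic Nerve Segmentation and Cross-Sectional Morphometry for 3D MRI
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for segmenting the optic nerve separately from its
    surrounding cerebrospinal fluid in high-resolution 3D T2-weighted MR
    volumes and for quantifying its diameter and cross-sectional area along
    an extracted centerline. Provides a synthetic phantom generator with
    analytic ground truth, eye-globe detection and volume-of-interest
    preprocessing, a CPU-trainable 3D U-Net with Dice loss and on-the-fly
    augmentation, segmentation evaluation metrics (Dice, tolerance Dice,
    HD95, average surface distance, ICC), maximal-inscribed-sphere centerline
    extraction with 0.1 mm cross-sectional profiling, and coronal-plane
    ablation plus agreement statistics against manual reference measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
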