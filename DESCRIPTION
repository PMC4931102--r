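Package: rpHAR
Title: Human Activity Recognition with Sparse Random Projections and
    Jaccard Density Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recognizes human activities and identifies subjects from
    6-axis wearable inertial sensor streams (tri-axial accelerometer and
    gyroscope). Sliding windows of raw signal are summarized by a
    catalogue of 99 time-domain and physical features; the
    high-dimensional feature vectors are mapped to a low-dimensional
    space by sparse Achlioptas random projections, each class is
    modelled by a product of per-dimension Gaussian kernel density
    estimates, and the projection whose class densities have the
    smallest Jaccard overlap is kept as the classifier. Includes
    ReliefF and Gaussian divergence feature-ranking baselines, a seeded
    synthetic IMU and feature-cluster generator, and a stratified
    cross-validation evaluation layer with confusion-matrix metrics and
    pairwise activity tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
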