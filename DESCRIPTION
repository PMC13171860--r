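Package: canopystack
Title: Indirect Forest Stock Volume Mapping from Sparse LiDAR Footprints
Version: 0.1.0
Authors@R:
    person("Canopystack", "Developers", email = "canopystack@example.org",
           role = c("aut", "cre"))
Description: Tools for wall-to-wall forest stock volume (FSV) estimation from
    discrete spaceborne-LiDAR footprints fused with optical and terrain
    predictors. Provides variogram estimation and model fitting, ordinary
    kriging, sequential Gaussian conditional simulation, exponent-optimized
    inverse-distance weighting (grid search, particle swarm, genetic
    algorithm), gray-level co-occurrence texture features, vegetation
    indices, terrain derivatives, a two-stage VIF + SHAP predictor screen,
    a multi-level stacking ensemble regressor with out-of-fold meta
    features, plot-volume temporal and areal harmonization, and a seeded
    synthetic-data generator so the whole pipeline is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
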