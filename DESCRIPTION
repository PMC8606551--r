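Package: reentryforge
Title: Synthetic Ventricular Geometries, Monodomain Programmed Stimulation,
    and Geometric-Feature Arrhythmia Risk Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico arrhythmia-risk workbench: generates synthetic
    ventricular geometries (2D slabs and voxelized left-ventricular shells)
    with AHA 17-segment maps, rule-based fibers and concentric graded ischemic
    border zones; augments model populations by peeling outer ischemic layers;
    runs an adaptive S1-S4 programmed-stimulation vulnerability protocol on a
    built-in monodomain reaction-diffusion solver with the ten Tusscher-
    Panfilov (2006) human ventricular ionic model including ischemic
    remodeling (reduced INa/ICaL, elevated extracellular potassium, an
    ATP-sensitive potassium current, reduced conductivity); and trains and
    compares seven machine-learning classifiers of per-segment arrhythmia
    inducibility from four geometric features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    class,
    e1071,
    rpart,
    xgboost,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
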