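Package: dynconn
Title: Whole-Brain Dynamical Modelling for Connectome-Based Patient
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates regional electrical brain activity with a delay-coupled
    two-population (excitatory/inhibitory) neural-mass network built on a
    structural connectome, converts it to BOLD signals through the
    Balloon-Windkessel hemodynamic model, and validates the model against
    functional connectivity over a (global coupling x global delay) parameter
    grid.  Provides neuroimaging model fitting (goodness-of-fit landscapes),
    behavioural model fitting (rank-sum effect-size maps with Gaussian
    smoothing and random-field thresholding), and a leakage-safe nested
    cross-validation pipeline with cross-validated confound regression and
    L1-penalised logistic regression for classifying patients against
    controls.  A synthetic-cohort generator with planted group effects makes
    every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    glmnet,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
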