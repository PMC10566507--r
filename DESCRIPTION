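Package: amideml
Title: Benchmarking Machine-Learned Yield Prediction for Carbodiimide
    Amide Couplings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for benchmarking reaction-yield prediction on
    carbodiimide-mediated amide couplings. Provides a reaction data model with
    CSV and conformer (SDF/XYZ) input/output, mechanism-derived augmentation
    (O-acylisourea intermediates, reaction-center annotation, amine
    classification), multimodal featurization (Morgan fingerprints, a 2D
    physicochemical descriptor battery, atomic environment vectors with
    sum-pooling, percent buried volume sterics, surrogate quantum-chemical
    reaction features including the electronic reaction energy), a model
    benchmark harness with fixed train/test splits and a four-block stacking
    ensemble, reactivity-cliff and uncertain-record auditing with filtered
    re-evaluation, and a synthetic literature-like dataset generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    glmnet,
    ranger,
    xgboost,
    e1071,
    nnet,
    jsonlite,
    methods,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
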