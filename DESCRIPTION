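Package: retinopipe
Title: Retinal Fundus Image Analysis for Diabetic Retinopathy and Macular Edema
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting diabetic retinopathy (DR)
    and diabetic macular edema (DME) in colour fundus photographs, built and
    validated on a bundled synthetic fundus generator. Stages: iterative
    expectation-maximization impulse denoising, Perona-Malik anisotropic
    diffusion for artifact removal, Harris hawks optimization (HHO) of a
    monotone contrast transform, optic-disc removal and OPTICS density-based
    blood-vessel segmentation, lesion candidate detection and
    structural/shape/orientation/colour feature extraction, a random-subspace
    ensemble of convolutional neural networks with weighted-average fusion
    and diversity statistics, and conditional-entropy severity grading from
    lesion counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    EBImage,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'architecture.R'
    'hho.R'
    'preprocess.R'
    'optics.R'
    'vessels.R'
    'features.R'
    'ensemble.R'
    'metrics.R'
    'io.R'
    'severity.R'
    'pipeline.R'
    'retinopipe-package.R'
    'synthetic-fundus.R'
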