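Package: msnet3d
Title: Multi-Task 3D Convolutional Networks for Lung-Nodule Malignancy
    Assessment with Collaborative Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements MS-Net, a two-stage multi-task 3D convolutional
    network for assessing lung-nodule malignancy from CT while modelling
    inter-observer disagreement. Stage one (FDID) couples a multi-kernel
    grouped-convolution residual backbone (3D-BcResNet50) with ten parallel
    prediction heads (eight semantic features plus individual and panel
    diagnoses); stage two (DR) refines the two diagnoses from the fused
    head predictions. Training uses a collaborative loss that softens
    one-hot targets by mixing each radiologist's label with the panel
    label. The package also provides LIDC-style annotation parsing and
    cohort rules, CT preprocessing (resampling, HU windowing, cube
    extraction), online augmentation with class rebalancing, the two-stage
    SGD schedule, evaluation metrics and cross-validation designs, and a
    synthetic 3D nodule-phantom generator with simulated readers so the
    whole pipeline is testable without any imaging-data download. All
    network primitives (grouped 3D convolution, batch normalisation,
    backpropagation) are implemented in C++/R within the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
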