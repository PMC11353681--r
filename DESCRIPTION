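Package: quanvnet
Title: Quanvolutional Neural Networks for Breast Ultrasound Image Classification
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.com>
Description: Hybrid quantum-classical image classification with quanvolutional
    layers: parameterized 9-qubit circuits act as 3x3 convolutional kernels over
    grayscale images, simulated exactly on a classical statevector backend.
    Provides an exact few-qubit simulator with analytic (parameter-shift and
    adjoint) gradients, angle embedding of image patches, a 15-parameter
    entangled SU(4)-style kernel circuit, a two-layer quanvolutional feature
    extractor with a dense classification head trained by Adam on binary
    cross-entropy, an architecture-matched classical CNN baseline, a
    BreastMNIST-compatible loader with the associated preprocessing pipeline,
    a synthetic speckled-ultrasound lesion generator, and confusion-matrix
    classification reports.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    caret
Config/testthat/edition: 3
RoxygenNote: 7.3.3
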