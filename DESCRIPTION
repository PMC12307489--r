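Package: hafusenet
Title: Motor-Imagery EEG Classification with Hybrid-Attention Feature Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end classification of four-class motor-imagery EEG
    (left hand, right hand, feet, tongue) with HA-FuseNet: a multi-scale
    dense convolutional branch carrying a hybrid variance-informed
    squeeze-and-excitation attention (svSE), an LSTM branch with a two-stage
    global self-attention module (SCoT: Non-local over channels followed by
    contextual-transformer temporal attention), depth-dimension feature
    fusion of the two branches, and an optional separable-ghost (SG)
    lightweight convolution variant. Includes BCI-Competition-IV-2A-style
    GDF/MAT readers, cue-locked epoching and normalization, a synthetic
    ERD/ERS recording generator for fully offline testing, Cohen's kappa and
    accuracy metrics, and within-subject and leave-one-subject-out
    cross-subject evaluation protocols. The network, reverse-mode automatic
    differentiation, and Adam optimizer are implemented natively with
    compiled kernels for the convolution and LSTM hot paths.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
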