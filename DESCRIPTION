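Package: repmlpnet
Title: Lightweight MobileNetV2 Networks with Re-Parameterized MLP Blocks for Leaf Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Building blocks, model assembly, profiling and a compact training
    harness for lightweight convolutional image classifiers aimed at crop
    leaf-disease recognition on edge devices. Implements depthwise-separable
    convolutions, inverted residual blocks, efficient channel attention (ECA),
    and an improved bottleneck in which a re-parameterized multilayer
    perceptron (RepMLP) performs feature extraction at reduced channel width.
    The RepMLP training-time convolution branches can be folded exactly into
    the partition fully connected layer for deployment (structural
    re-parameterization). A parameter/FLOP profiler under a pinned counting
    convention, a synthetic leaf-image generator with augmentation-based class
    balancing, and an SGD plus cosine-annealing training loop make the whole
    pipeline reproducible without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
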