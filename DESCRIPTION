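Package: gaitfuse
Title: Hybrid Skeleton, Joint-Angle and Gait-Parameter Fusion for
    Pathological Gait Recognition
Version: 0.1.0
Authors@R:
    person("gaitfuse", "developers", email = "gaitfuse@example.org",
           role = c("aut", "cre"))
Description: Tools for recognising pathological gait patterns from 3-D
    skeleton sequences recorded by a depth camera. Implements the full
    feature-extraction pipeline (joint bending angles, link angles,
    basic, phase-based and angle-based gait parameters with coordinate
    based gait-event detection), a three-branch hybrid neural network
    (a spatial-temporal graph convolutional encoder for raw skeleton
    sequences, a multilayer LSTM encoder for joint-angle sequences and
    a feed-forward encoder for gait parameters, fused into a softmax
    classifier), a parametric kinematic simulator for six gait classes
    (normal, antalgic, steppage, lurching, stiff-legged, Trendelenburg)
    plus a vestibular-like binary dataset, and subject-disjoint
    cross-validation with standard binary classification metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
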