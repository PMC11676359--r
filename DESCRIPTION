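Package: lorentznet
Title: Hybrid Euclidean-Lorentz Convolutional Image Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and compares convolutional image classifiers whose decoder
    operates either in Euclidean space or on the Lorentz model of hyperbolic
    space (a shared convolutional encoder with feature clipping, an exponential
    map onto the curvature-parameterized hyperboloid, and a hyperbolic
    multinomial-logistic head with learnable curvature). Includes exact Lorentz
    geometry primitives, a synthetic hierarchical image generator with a known
    class taxonomy, embedding-organization statistics (geodesic class-distance
    matrices, mean absolute difference to a ground-truth hierarchy with
    bootstrap intervals, Spearman rank alignment, dendrograms), projected
    gradient descent adversarial robustness sweeps, and out-of-sample /
    zero-shot evaluation rules with patient-level aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
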