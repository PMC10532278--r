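Package: localsem
Title: Local Structural Equation Models over a Continuous Moderator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of structural equation model parameter curves as
    smooth functions of a continuous moderator (e.g. age) via kernel-weighted
    conditional covariance matrices at a grid of focal points. Supports
    pointwise estimation, joint estimation with invariance and polynomial
    parameter constraints, multiple-group discretization, and estimation of
    differential item functioning (DIF) effects for parameters held invariant.
    Inference on parameter-curve variation is provided through nonparametric,
    cluster, and replication-design bootstrap, a bias-corrected standard
    deviation test, Wald equality and functional-form tests, and a permutation
    test. Includes generators for exact-moment synthetic populations and a
    Monte Carlo harness for bias/RMSE and type-I-error/power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
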