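Package: ldnet
Title: Latent Gaussian Copula Differential Network Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of differential networks (differences of two groups'
    precision matrices) for continuous, binary and mixed data under latent
    Gaussian copula models. Latent correlation matrices are estimated by
    rank-based Kendall's tau statistics combined with bridge-function
    inversion, and the difference of the two precision matrices is estimated
    directly by constrained elementwise l1 minimization solved with an
    alternating direction method of multipliers (ADMM) in symmetric-vectorized
    form. Includes AIC-style tuning with sup-norm, Frobenius and spectral
    losses, support-recovery thresholding, hub-network simulation scenarios,
    support-recovery and estimation-error metrics, ROC curves, a replication
    harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    jsonlite,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    withr
Config/testthat/edition: 3
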