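Package: hmpt
Title: Hierarchical Bayesian Multinomial Processing Tree Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits hierarchical multinomial processing tree (MPT) models to
    participant-by-category frequency data using Markov chain Monte Carlo.
    Two population models are provided: the beta-MPT, with independent beta
    distributions for each individual-level parameter, and the latent-trait
    MPT, with a multivariate normal distribution on probit-transformed
    parameters and a scaled inverse-Wishart prior on the covariance matrix.
    Models are read from EQN files with optional equality and constant
    restrictions.  The latent-trait model supports continuous covariates and
    discrete factors as predictors on the probit scale.  Also included are
    participant-homogeneity tests (asymptotic chi-square and item-wise
    permutation), posterior-predictive fit statistics (T1, T2, PPP values),
    DIC, within- and between-subjects comparisons, sampling-error-corrected
    population correlations, and synthetic-data generators for parameter
    recovery simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
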