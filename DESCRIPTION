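Package: pupilql
Title: Pupillometry of Value-Based Decision Making with Hierarchical Q-Learning
Version: 0.1.0
Authors@R: person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for analysing pupil size dynamics
    during probabilistic reinforcement learning. Simulates the probabilistic
    selection task and softmax Q-learning agents with asymmetric learning
    rates, fits the hierarchical Bayesian two-learning-rate Q-learning model
    to choice data via MCMC with probit-transformed subject parameters,
    preprocesses continuous pupil recordings (blink interpolation, Butterworth
    band-pass, per-run standardisation, nuisance IRF regression), estimates
    deconvolved event-related pupil responses with single-trial value and
    reward-prediction-error covariates by cross-validated ridge regression,
    and performs group-level inference with cluster-based permutation tests
    and bootstrapped across-subject regressions. Includes a synthetic-data
    generator with known ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
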