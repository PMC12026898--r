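Package: ficsurr
Title: Feedback-Inhibition-Control Mean-Field Brain Simulation with
    Surrogate-Assisted Evolutionary Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates whole-brain resting-state dynamics with the
    feedback-inhibition-control (FIC) dynamic mean-field model coupled
    through a structural connectome, converts neural activity to BOLD via a
    Balloon-Windkessel hemodynamic forward model, and scores model realism
    against empirical functional connectivity (FC) and functional
    connectivity dynamics (FCD) with the (1-r)+d+KS cost. Model coefficients
    are fitted with a covariance matrix adaptation evolution strategy
    (CMA-ES) whose expensive numerical-integration step can be replaced by
    deep surrogate networks: a within-range firing-rate classifier and an
    FC+FCD cost predictor built on an embedding-addition multilayer
    perceptron architecture. Includes a synthetic fixture generator
    (connectomes, covariate maps, self-generated empirical targets) for
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
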