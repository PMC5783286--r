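Package: resolvemsm
Title: Multistate Models with a Latent Resolved State for Panel Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits continuous-time Markov multistate models in which the
    symptom-free state of a chronic disease process is split into a transient
    "temporary non-disability" state and a latent absorbing "resolved" state
    that is never directly observed. Observations of "no disability" at clinic
    visits are ambiguous between the two, and the likelihood marginalises over
    all latent assignments by a forward recursion over censored state sets.
    Provides maximum-likelihood estimation under intermittent (panel)
    observation with proportional-hazards covariate effects on the transition
    intensities, Wald intervals, a boundary likelihood-ratio test for the
    existence of resolution, estimated probabilities of having resolved, a
    continuous-time path simulator, and a reproducible simulation-study
    harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
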