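Package: ssrace
Title: Stop-Signal Race Modelling and Locus Coeruleus Contrast Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of the stop-signal
    task with an ex-Gaussian race model that includes trigger-failure and
    go-failure mixtures, yielding posterior distributions of the stop-signal
    reaction time (SSRT). Includes an adaptive-staircase task simulator for
    control and drug-crossover cohorts, a differential-evolution MCMC sampler
    with migration and split-chain convergence diagnostics, posterior
    predictive checks, neuromelanin contrast-to-noise ratio (CNR)
    quantification of the locus coeruleus from 3D volumes (semi-automated
    5-SD segmentation, probabilistic atlas construction, subdivision
    summaries, synthetic phantoms), and the final association stage: linear
    mixed models testing whether locus coeruleus CNR moderates a drug effect
    on SSRT.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    lme4,
    lmerTest,
    pbkrtest,
    car,
    jsonlite,
    yaml,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
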