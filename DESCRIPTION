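Package: coevauth
Title: Phylogenetic Coevolution of Religious and Political Authority
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian phylogenetic comparative methods for the coevolution of
    two ordinal traits on language phylogenies, motivated by the study of
    religious and political authority in Austronesian societies. Provides a
    bivariate ordinal phylogenetic mixed model of signal and correlation on
    the liability scale, a dynamic coevolutionary model in which latent
    traits evolve under a bivariate Ornstein-Uhlenbeck process with
    cross-trait selection, ordinal probit observation and a spatial Gaussian
    process control, and constrained four-state Markov models of sequential
    evolution compared by stepping-stone marginal likelihoods and Bayes
    factors. Includes seeded synthetic-data generators (birth-death trees,
    thresholded OU trajectories, CTMC tip states, spatial coordinates) so
    that every stage of the pipeline is testable without external data,
    plus shared MCMC machinery (adaptive Metropolis, split R-hat, effective
    sample size, HPD intervals, Savage-Dickey Bayes factors).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
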