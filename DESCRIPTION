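Package: socpools
Title: Multi-Pool Soil Organic Carbon Decomposition Models for Laboratory Incubations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing laboratory soil-incubation CO2 flux data with
    two- and three-pool first-order carbon decomposition models. Converts raw
    jar-headspace CO2 concentration changes into SOC-normalised release rates,
    fits pool fractions and decay constants by Metropolis-Hastings MCMC under
    uniform priors and a heteroscedastic Gaussian likelihood, compares nested
    pool structures by AIC, projects short- and long-term cumulative CO2-C
    release with per-pool attribution, and performs regional permafrost
    warming-risk upscaling. Includes a seeded synthetic-data generator that
    emulates a permafrost incubation cohort for parameter-recovery and
    model-selection experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
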