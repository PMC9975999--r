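Package: twinfear
Title: Twin Modelling of Fear Conditioning Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives differential expectancy-rating phenotypes (initial
    development, consolidation and extinction of conditioned fear) from
    trial-level fear-conditioning data, computes zygosity-specific twin
    descriptives with bootstrap confidence intervals, and fits trivariate
    ACE/AE Cholesky biometric models by full-information maximum likelihood
    over monozygotic and dizygotic families, including incomplete pairs and
    singletons. Includes a synthetic twin-data generator with known
    additive-genetic/non-shared-environment structure so the full pipeline
    can be exercised and validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
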