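Package: arealrisk
Title: Small-Area Disease Mapping with Leroux CAR Spatial Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for ecological (areal) epidemiological analysis of
    health-outcome counts: indirect age-sex standardization and
    standardized morbidity ratios (SMRs), k-nearest-neighbour and
    grid-contiguity spatial weights with GAL neighbour-file support,
    global and local Moran's I with Monte-Carlo permutation inference and
    Bonferroni-corrected LISA cluster classification, variance inflation
    factor screening with step-wise deletion, and Bayesian Poisson
    log-linear regression with Leroux conditional autoregressive (CAR)
    spatial random effects fitted by Metropolis-within-Gibbs MCMC,
    reporting relative risks with 95 percent credible intervals and
    residual autocorrelation checks.  A synthetic areal study generator
    with recorded ground truth supports end-to-end validation and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
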