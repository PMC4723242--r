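Package: facint
Title: Latent-Variable Indexes of HIV and Reproductive Health Service
    Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes facility-level indexes of HIV and reproductive-health
    (RH) service integration from client-flow and facility activity data.
    Eight integration attributes (service availability in the MCH/FP unit and
    facility, multi-service rooms and providers, HIV-treatment location,
    day-level co-delivery, and client-level co-receipt within a consultation
    or visit) are computed from raw records, coded as ordinal indicators, and
    combined by Bayesian confirmatory factor analysis with probit links for
    ordinal data, estimated by a data-augmentation Gibbs sampler. The package
    provides convergence (potential scale reduction) and posterior-predictive
    fit diagnostics, standardized loadings, plausible-value facility scores
    with ranks and a 1-7 graphing rescale, fixed-parameter cross-wave scoring,
    baseline-vs-endline change metrics, and a synthetic-study generator for
    validating every pipeline stage against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mvtnorm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
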