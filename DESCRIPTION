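Package: blcda
Title: Bayesian Latent Class Models for Diagnostic Test Accuracy Without a Gold Standard
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates true disease prevalence and the sensitivity and
    specificity of multiple binary diagnostic tests when no gold standard
    is available, using two-class Bayesian latent class models that allow
    pairwise conditional dependence between tests via additive within-class
    covariances. Includes a seedable Metropolis-within-Gibbs sampler with
    burn-in step-size adaptation, Beta prior elicitation from a central
    value and a percentile, convergence diagnostics, posterior-predictive
    cell checks, Youden-index summaries, ROC-based optimal cutoff selection
    for continuous scores, and simulators for correlated dichotomous test
    panels and two-component score distributions. Ships the cross-classified
    MoCA/MMSE/ADAS-cog count tables and informative priors of a published
    Alzheimer's disease and mild cognitive impairment screening analysis as
    worked fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rjags,
    coda,
    jsonlite,
    optparse
Config/testthat/edition: 3
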