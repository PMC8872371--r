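Package: cptrisk
Title: Cumulative Prospect Theory Analysis of Risk Perception from
    Certainty Equivalents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying decision-making under loss risk with
    cumulative prospect theory (CPT). Implements the one-parameter
    power value function and Tversky-Kahneman probability weighting
    function, elicitation of behavioral parameters (loss scale, value
    curvature, weighting curvature) from certainty-equivalent survey
    responses by Bayesian MCMC nonlinear regression, a hierarchical
    extension linking per-respondent parameters to sociodemographic
    covariates, and a synthetic-cohort generator that emulates a
    327-respondent long-term-care-facility manager survey for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
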