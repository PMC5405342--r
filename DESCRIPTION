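Package: adaptenrich
Title: Stratified Adaptive-Enrichment Two-Stage Designs for Phase II Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact evaluation and optimisation of stratified adaptive-enrichment
    Simon-type two-stage designs for single-arm Phase II trials with a binary
    endpoint and a dichotomous predictive biomarker. Computes exact binomial
    rejection probabilities for the three positive trial outcomes (reject both
    nulls in the unselected population, reject the biomarker-positive null
    without enrichment, reject it after enrichment), familywise type-I error,
    overall power, expected sample size under futility-only or
    futility-plus-efficacy stopping, and the probability of early termination.
    Includes an independent full-enumeration oracle and a Monte-Carlo trial
    simulator for verification, and a pruned exhaustive search over the
    10-parameter design space for the design minimising expected sample size
    under the global null subject to error-rate constraints. A command-line
    interface covers evaluation, search, simulation and rejection-curve export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
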