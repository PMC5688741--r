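Package: worklife
Title: Worklife Expectancy from Multi-State Labor-Market Event Histories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates worklife expectancy (WLE) and state-specific expected
    durations from long-format (counting-process) multi-state event histories.
    Two estimation routes are provided: a nonparametric multi-state life table
    built from occurrence/exposure ratios at observed event ages, and a
    Cox-regression-adjusted life table in which transition-stratified
    proportional-hazards fits supply Breslow baseline hazards that are
    multiplicatively adjusted for a covariate profile. Occupation
    probabilities come from the Aalen-Johansen product integral, with
    Greenwood-type covariance recursion for pointwise confidence limits and
    confidence bounds on expectancies as areas under the pointwise limits.
    Includes stabilized inverse-propensity weighting for exposure and
    censoring, and a register-style cohort simulator with exact matrix-
    exponential truth oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
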