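Package: dcar
Title: Quadratic-Regression Tests of Developmental Constraints and
    Adaptive Response Hypotheses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing developmental-constraints ("silver spoon") and
    adaptive-response (environmental mismatch) hypotheses about early-life
    effects on adult fitness outcomes. Builds conditional risk-set panels
    (conception, live birth, infant survival) from longitudinal rainfall,
    dominance-rank and reproductive records; fits quadratic linear probability
    models of adult outcomes on the developmental environment and the
    developmental/adult environment difference, with group or individual fixed
    effects and cluster-robust (CR1) standard errors; computes derivative-based
    marginal-effect tests of both hypotheses, percentile effect translations,
    and a delta-sign asymmetry test; adjusts families of tests with sharpened
    two-stage false-discovery-rate q-values; and ships a synthetic-panel
    generator for power and size simulation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    lubridate,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
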