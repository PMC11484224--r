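Package: drgsd
Title: Two-Stage Group-Sequential Designs with Delayed Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Planning and evaluation of two-stage group-sequential clinical
    trial designs when outcomes are observed with a lag, so that patients are
    still "in the pipeline" at the interim analysis.  Computes error-spending
    decision boundaries for the standard group-sequential design (GSD), the
    delayed-response design of Hampson and Jennison (2013)
    <doi:10.1111/j.1467-9868.2012.01030.x> with a nonbinding recruitment
    stopping boundary (DR-GSD), and the repeated-rejection variant (RR-GSD);
    evaluates global operating characteristics (stopping probabilities, power,
    expected sample size including pipeline patients, conditional power)
    analytically under the canonical multivariate normal model; and validates
    them by Monte-Carlo simulation of either the test statistics directly or
    synthetic patient-level trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mvtnorm,
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
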