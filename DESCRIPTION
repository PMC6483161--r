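Package: riskstrat
Title: Clinical Utility of Risk-Stratified Intervention with Polygenic Scores
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form calculator for the clinical utility of targeting an
    intervention to the tail of a polygenic risk score distribution. Given
    disease prevalence, the fraction of the population targeted, and one
    discrimination parameter (remainder-referenced relative risk, sensitivity,
    or precision), computes the full 2x2 classification summary
    (PPV, NPV, sensitivity, specificity, accuracy), prevention fractions, and
    the number needed to treat, with optional differential treatment
    effectiveness inside and outside the target group. Includes a Gaussian
    liability-threshold model for risk-by-percentile curves, a Monte Carlo
    cohort simulator that validates every closed form by counting, a
    config-driven scenario-table engine, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
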