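Package: valcorr
Title: Correcting the Predictive Validity of Selection Tests for
    Compensatory Selection and Range Restriction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the predictive validity of an admission or selection
    test from incumbent-only outcome data, correcting for the two artifacts
    that attenuate the naive predictor-outcome correlation: reciprocal
    suppression induced by compensatory selection on a weighted composite,
    and direct or indirect range restriction.  Implements Thorndike's case A
    and case C formulas, the Pearson-Lawley multivariate correction, maximum
    likelihood estimation via the EM algorithm for the trivariate normal with
    missing outcomes, multiple imputation by chained equations with Bayesian
    linear regression, and the Hunter-Schmidt stepwise classical-test-theory
    procedure.  Includes a trivariate-normal applicant-pool simulator with
    top-fraction composite selection and a Monte Carlo harness that compares
    the correction methods by bias and root mean square error across
    selection rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
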