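Package: adaptenrich
Title: Bayes-Optimal Adaptive Enrichment Designs for Two-Stage Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of two-stage adaptive enrichment Phase III
    clinical trials with a pre-specified biomarker subpopulation. Implements a
    familywise-error-controlling closed testing procedure built from Simes
    intersection tests and weighted inverse-normal combination tests, the
    Bayes-optimal interim enrichment decision computed by Monte Carlo under
    one-point or bivariate normal priors, an adaptive square-subdivision mapper
    for the interim decision boundary, and Monte Carlo / analytic operating
    characteristics for the adaptive design and its fixed full-population and
    fixed subpopulation comparators.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse,
    yaml
Config/testthat/edition: 3
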