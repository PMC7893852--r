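Package: frailscan
Title: Frailty Case Definitions over Linked Primary-Care and Administrative Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying frailty in older adults from routinely
    collected health data. Implements an electronic-medical-record (EMR)
    case definition expressed as a configurable boolean rule over
    diagnosis-code, medication-code and free-text atoms with a multi-year
    lookback; a three-rule administrative definition (long-term-care
    residence, terminal illness, and multiple modified Edmonton Frail
    Scale indices); deterministic person-level linkage with identifier
    scrambling; cohort inclusion criteria with registry-coverage
    fractions; rolling-window chronic-condition classification;
    descriptive tables over mutually exclusive frailty groups; and a
    CHAID (chi-square automatic interaction detection) decision-tree
    learner with bootstrap complexity selection and cross-validated
    validity metrics. A synthetic-cohort generator produces paired EMR
    and administrative bundles from a latent 1-9 frailty continuum so the
    whole pipeline is testable without access to real health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    readr,
    tibble,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
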