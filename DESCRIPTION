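Package: validrelax
Title: Validation Relaxation for Electronic Survey Data Quality Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality assurance for electronic data collection by "validation
    relaxation": validation rules on a purposive subset of survey questions are
    intentionally removed so that data recording errors become committable and
    detectable. The package models the survey instrument (ordered questions,
    skip-logic relevance, relaxed-rule declarations), evaluates an eight-class
    taxonomy of detectable errors over submission records, computes
    opportunity-denominated error rates with Wilson confidence intervals,
    produces per-enumerator and temporal monitoring reports with a
    between-group analysis of variance, and fits logistic error-rate trends
    with a cluster-robust sandwich variance estimator. A synthetic survey
    generator reproduces a reference cluster-survey fixture exactly and
    simulates datasets from a configurable logistic error process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
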