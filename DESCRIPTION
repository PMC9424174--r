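Package: occupex
Title: Occupational Exposure Scoring and Case-Control Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for survey-based occupational exposure assessment in
    case-control studies. Converts per-job exposure questionnaire responses
    into normalized exposure scores for nine contaminant classes via a
    configurable schema (exposure types, factors, item weights), aggregates
    them to participant-level ever and duration-adjusted scores over job
    histories, triages Standard Occupational Classification (SOC) job codes
    merged from dual autocoders, tabulates job-years by occupational major
    group and pre-onset time window, and fits the full association battery:
    permutation tests, covariate-adjusted logistic regressions, adaptive
    elastic net and adaptive lasso variable selection, enrichment tests of
    case proportions, Benjamini-Hochberg correction, and linear models of
    exposure on job-years. Includes a seeded synthetic cohort generator with
    planted effects so the entire pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
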