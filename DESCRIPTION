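Package: hncmeta
Title: Sex/Gender and HPV Mention Analysis of Head and Neck Cancer Trial Registrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A meta-research pipeline for quantifying how sex and/or gender
    (S/G) and human papillomavirus (HPV) are considered in head and neck
    cancer (HNC) clinical-study registrations. Reads AACT-style relational
    exports of ClinicalTrials.gov, selects an HNC cohort by rule-based
    condition-string matching, classifies each study's S/G mention
    hierarchically (analytical variable, recruitment-only, no mention), tags
    HPV mention and HPV-relevant subsites, derives design strata
    (controlled/uncontrolled, randomized, phase, enrolment, status), and
    computes the associated contingency-table statistics: Pearson chi-square
    or Fisher exact tests and cross-product odds ratios with Wald confidence
    intervals, plus yearly submission trends. Includes a seeded synthetic
    registry generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
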