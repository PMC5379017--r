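Package: cd30screen
Title: Biomarker Prescreening of Clinical-Genomic Warehouses for
    CD30-Positive Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate gene-expression-based prescreening of a
    clinical-genomic warehouse for tumors expressing a target biomarker
    (CD30).  Computes global expression Z-scores and trichotomizes samples
    into low/medium/high RNA groups, applies an ordered cohort-eligibility
    funnel, tests tissue-of-origin enrichment of biomarker-high samples
    with a two-sided Fisher exact test, scores immunohistochemistry
    staining profiles into composite H-scores and positivity calls, and
    quantifies how well high RNA expression predicts protein positivity
    (sensitivity, specificity, predictive values, accuracy).  Includes a
    seeded simulator of synthetic patient warehouses calibrated to
    published per-tissue expression summaries, funnel attrition rates and
    RNA-group-conditional protein-positivity rates, so that every stage of
    the pipeline is testable without access to real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    caret,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
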