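Package: lateraleye
Title: Detecting Wrong-Site Surgery from Claims Laterality and
    Procedure-Diagnosis Association Outliers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for screening inpatient claims for potential wrong-site
    surgery. Extracts body part and laterality from coded ICD-10-PCS
    procedures and ICD-10-CM diagnoses through an extensible prefix map,
    classifies claims into laterality subgroups, and flags
    procedure-diagnosis mismatches two ways: a rule-based laterality
    conflict flag and an association-outlier model that scores how well
    each procedure is substantiated by the recorded diagnoses using
    smoothed co-occurrence statistics learned from a training corpus.
    Includes a condition-first synthetic claims generator with planted
    wrong-site errors and full ground truth, an automated clinical-review
    rule engine, precision-recall threshold selection, CMS-style small-cell
    suppression, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
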