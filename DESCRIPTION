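Package: ardsdefer
Title: Physician-AI Collaboration Strategies for ARDS Chest X-Ray Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how physicians and an AI classifier can share
    the work of identifying acute respiratory distress syndrome (ARDS) findings
    on chest X-rays. Implements the ordinal 1-8 assessment scale and its linear
    correspondence with classifier probabilities, consensus and
    leave-one-reader-out reference standards from multi-reader panels,
    rule-based deferral and blending strategies with review-burden accounting,
    per-reader evaluation with patient-level cluster-bootstrap confidence
    intervals and a one-sided paired bootstrap test, and a seeded synthetic
    reader-study generator that emulates the clustered cohort structure of a
    multi-reader ARDS chest X-ray study so the full pipeline can be exercised
    and validated without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
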