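Package: mnhimpact
Title: Decision-Tree Cohort Modelling of Maternal, Fetal, and Neonatal
    Intervention Impact
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A deterministic decision-tree cohort model for comparing the
    impact of maternal and neonatal health interventions on expected
    maternal, fetal, and neonatal deaths across home, clinic, and hospital
    care settings. An annual cohort of pregnancies is propagated through
    cause-specific sub-conditions via a prevention, diagnosis, transfer,
    and treatment cascade, with intervention receipt decomposed into
    penetration (availability), utilization (appropriate use), and
    efficacy. Supports layered and sequential-line intervention
    composition, lives-saved comparisons between scenarios, incidence
    calibration against historical no-intervention mortality, high/low
    sensitivity bounds, and an independent individual-level Monte Carlo
    oracle for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
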