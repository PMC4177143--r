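Package: temporalSN
Title: Temporal Clinical Data Mining with Association Rules and the SN
    State-Prediction Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-phase mining of longitudinal clinical laboratory panels.
    Phase one discovers association rules between discretized kidney and
    liver function analytes (Creatinine, BUN, SGOT, SGPT, haemoglobin) and
    a disease state using a level-wise Apriori miner with exact
    count-based support and confidence. Phase two implements the SN
    algorithm: per-temporal-point finite-difference derivative vectors of
    the rule-selected parameters, a differential-area (Jacobian
    determinant / Gram wedge) statistic between consecutive temporal
    points, data-driven threshold calibration, and sequential prediction
    of the disease state at the next temporal point. Includes a
    deterministic reconstruction of a published brain-tumour rule table
    as a transaction fixture, a synthetic longitudinal cohort simulator
    with known state dynamics for recovery experiments, and an
    end-to-end pipeline from raw panels to predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
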