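Package: synthpool
Title: Partially Synthetic Data Pooling for Cross-Country Health Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooling harmonized health-survey microdata across
    jurisdictions when one partner's records cannot leave their country.
    Implements sequential tabular data synthesis with calibrated gradient
    boosted trees (beta calibration of class probabilities, normal-score
    transforms for continuous variables), partial-synthesis combining rules
    for inference across synthetic replicates, a membership-disclosure
    privacy attack with relative F1 scoring, an exact federated least-squares
    oracle via sufficient-statistic exchange, standardized-mean-difference
    balance diagnostics, and a two-country survey simulator with a modified
    CANHEART cardiovascular-health outcome for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    jsonlite,
    lhs,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
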