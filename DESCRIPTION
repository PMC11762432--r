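Package: hanEHR
Title: Hierarchical Attention Recurrent Networks for Longitudinal
    Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts health outcomes (all-cause mortality, nursing-home
    admission, home-care need) in ageing populations from irregularly
    sampled, annually aggregated primary-care records. Implements a
    mask-aware hierarchical attention recurrent network (GRU or LSTM) with
    variable-level and time-level attention, double masking for
    zero-padded periods and unrecorded values, a dynamic-cohort
    tensorization pipeline, a split/grid-search/retrain protocol,
    bootstrap-interval evaluation with calibration tables, cross-sectional
    baseline comparators, population- and patient-level attention maps,
    and a seeded synthetic cohort generator with planted, recoverable risk
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    Rcpp,
    ranger,
    stats,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    arrow,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
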