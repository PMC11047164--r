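Package: balanceN1
Title: Detecting Cortical N1 Potentials Preceding Natural Balance Corrections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting naturally occurring postural instabilities from
    anterior-posterior center-of-pressure dynamics and for identifying the
    low-amplitude fronto-central N1 cortical potential that precedes corrective
    balance responses. Implements center-of-pressure velocity (three-point
    central difference), distance- and time-to-boundary stability measures,
    threshold-based instability event detection with zero-crossing
    localisation, N1 trough and control trough harvesting from a cleaned EEG
    independent-component trace, epoch feature extraction (median absolute
    COPv, shear force, head acceleration, time-to-boundary), and a
    leave-one-subject-out gradient-boosting classification protocol with
    balanced undersampling, inner grid search, and Shapley-value feature
    importance. A seeded synthetic standing-balance cohort generator with
    sway-referenced support gain emulates the experimental task so the whole
    pipeline is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
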