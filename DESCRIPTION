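Package: hyperti
Title: Brain-to-Brain Synchrony from EEG Hyperscanning via Normalized Total Interdependence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-subject EEG hyperscanning of team
    interactions. Estimates brain-to-brain synchrony with total
    interdependence (TI), a coherence-based spectral dependence measure,
    normalized against a permutation null that destroys cross-subject
    epoch alignment. Includes a synthetic-data generator with controllable
    pairwise coherence, planted artifacts, audio-lag alignment of
    recordings, robust (golden-SD) epoch rejection, aggregation of pair
    TI to student and group levels, two-rater TeamSTEPPS score scaling
    with ICC(2,1) interrater reliability, and a correlation grid against
    team scores with Minimum Covariance Determinant outlier screening and
    Benjamini-Hochberg correction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    MASS,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
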