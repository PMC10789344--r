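Package: vltkit
Title: Automated Scoring, Process Scores and Diagnostic Analysis for the
    15-Word Verbal Learning Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores recall transcripts of the 15-word Verbal Learning Test
    (a Rey Auditory Verbal Learning Test adaptation) against target word
    lists, computes a catalog of process-score features (serial-position
    region counts, learning slopes, item consistency, subjective
    organization, serial clustering, recall timing), quantifies agreement
    between clinician-derived and automatic-speech-recognition-derived
    scores via intraclass correlation with confidence intervals, ranks
    features by Mann-Whitney rank-biserial effect sizes, and evaluates
    diagnostic discrimination of subjective cognitive decline versus mild
    cognitive impairment or dementia with extremely randomized tree
    ensembles under leave-one-out cross-validation, including DeLong
    confidence intervals and paired AUC tests.  A synthetic cohort
    generator with group-dependent learning curves, serial-position
    structure, consolidation, recognition responding, output-order
    dynamics, word timing, and a speech-rate-dependent word-miss process
    makes the full pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
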