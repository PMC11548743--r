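Package: ratduet
Title: Paired-Rat Social Behavior and Ultrasonic Vocalization Analysis at
    Light/Dark Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-tracking analysis pipeline for dyadic rat social behavior
    and ultrasonic vocalizations (USVs) recorded around light/dark
    transitions. Computes a compact 111-column geometric feature set (two
    convex-hull polygon features plus 109 centroid, hull, distance,
    movement, angle and detection-probability features) from two-animal
    pose-estimation tracks; trains and applies per-frame random-forest
    classifiers for 11 social and non-social behaviors with
    precision-recall threshold selection; types 50-kHz and 22-kHz calls
    (FLAT, FM, SHORT, ALARM) by duration/bandwidth rules; aligns call
    events with video frames on a common 12-fps timeline; aggregates
    durations, call counts and behavior-call co-occurrences over 1-minute
    epochs; and runs rank-transform 2x2 within-subject repeated-measures
    ANOVAs with partial eta squared. A seeded synthetic-data generator
    emulates pose tracks, call detection tables and session indexes with
    known ground truth so the full pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    ranger,
    nortest,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
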