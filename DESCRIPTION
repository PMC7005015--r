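Package: dyadscan
Title: Face Orienting and Face Scanning in Head-Mounted Eye Tracking of Dyadic Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for head-mounted eye-tracking recordings of
    face-to-face conversations: dispersion-based (I-DT) fixation detection at
    60 Hz, propagation of a tracked face quadrilateral across scene frames with
    point-count and frame-budget re-detection rules, classification of
    fixations into upper/lower face regions, coding of speaking and listening
    periods with cropping and interruption rules, speech-conditioned
    region-of-interest statistics (mixed ANOVA, exact nonparametric follow-ups,
    trait correlations), remapping of face-directed gaze onto a normalised face
    template, Gaussian-smoothed gaze density maps, and cluster-based Monte
    Carlo permutation tests of group differences. Includes a synthetic-data
    generator producing two-group cohorts with known ground truth so the whole
    pipeline is testable without scene video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
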