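Package: hfstrat
Title: Beat-to-Beat RR-Interval Features for Stratifying Atrial
    Fibrillation-Induced Heart Failure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discriminating atrial-fibrillation patients with
    AF-induced heart failure from AF controls using only beat-to-beat
    RR-interval statistics.  Provides ingestion and segmentation of 24-hour
    RR-interval streams into 5-minute windows with circadian (day/night)
    tagging; fourteen heart-rate-variability features per segment (time-domain
    statistics of the RR and relative-RR series, phase-rectified signal
    averaging deceleration/acceleration capacity and deceleration reserve,
    and Shannon, sample and spectral entropies); a synthetic AF cohort
    generator with tunable class effects for end-to-end testing;
    correlation-gated greedy forward feature selection driven by
    patient-grouped cross-validation of a decision-tree classifier with
    uniform class priors; segment- and patient-level evaluation with
    majority-vote patient stratification; and exact interventional tree
    Shapley feature-importance estimation with resampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    rpart,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
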