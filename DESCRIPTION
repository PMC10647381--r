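Package: hrvcohort
Title: Artifact-Robust Heart Rate Variability Analysis for Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for computing time-domain and Poincare heart rate
    variability (HRV) from beat-annotation streams in the presence of
    ectopic beats and recording artifacts. Implements relative-change
    NN-interval cleaning with minimum-run filtering, the Average and
    Combined segment-aggregation methods, sliding-window analysis over
    short-, medium- and long-term durations, cohort-level age and gender
    dependency modelling, quartile normal-range estimation with a
    rank-based evaluation methodology, and a seeded synthetic RR-interval
    cohort generator for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
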