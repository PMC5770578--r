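Package: actitraj
Title: Activity-Tracker Step Streams, Physical Activity Patterns, and
    Longitudinal Activity Trajectories in Inflammatory Arthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing minute-level step counts from wrist-worn
    activity trackers in cohorts of patients with rheumatoid arthritis or
    axial spondyloarthritis. Provides ingestion and validity filtering of
    minute step streams (full-day rule, 90-day observation window,
    adherence threshold), derivation of daily activity patterns from step
    cadence (total activity, moderate-to-vigorous activity, morning-step
    proportion), WHO physical-activity recommendation scoring, missing-day
    imputation by weekday means, K-means clustering of longitudinal
    activity trajectories with partition-quality criteria, mixed-model and
    logistic-regression group comparisons, a two-sample design sample-size
    calculation, and a synthetic-cohort generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    nlme,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
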