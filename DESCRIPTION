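Package: eegdyn
Title: Temporal Dynamics of Rest and Stimulus-Evoked EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of rest-stimulus interaction in multichannel EEG:
    resting-state peak frequency, its coefficient of variation, and band
    power estimated from the analytic signal; trial-to-trial variability
    (TTV) quenching/enhancement around stimulus onset; Lempel-Ziv (LZ76)
    complexity of median-binarized pre- and post-stimulus windows; and
    task-locked frequency and power sliding with fixed area-under-curve
    windows. Includes a seeded two-group auditory-oddball EEG simulator
    with the statistical structure the analysis assumes, nonparametric
    group comparison (two-sample Kolmogorov-Smirnov), Spearman rank
    correlation, Benjamini-Hochberg false-discovery-rate control, and a
    cohort-level pipeline that emits tidy result tables.
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
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
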