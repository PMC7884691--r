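Package: timefront
Title: Interval-Timing Behavior and Midfrontal EEG Rhythm Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying timing variability and cue-evoked midfrontal
    low-frequency EEG rhythms in clinical cohorts. Provides a calibrated
    synthetic-data generator (two-group interval-timing cohorts with
    cognition-linked timing variability and partially phase-locked delta
    bursts on 1/f EEG background), behavioral precision metrics (keypress
    coefficient of variation, trial-count inclusion filters, density
    summaries), a Morlet wavelet time-frequency engine with decibel baseline
    normalization, time-frequency regions of interest, inter-trial phase
    clustering and cluster-corrected t maps, event-related potential features
    (peak-to-trough components, contingent negative variation), and the
    statistical linking chain: group t tests with Cohen's d, Spearman
    correlations with Fisher r-to-z comparison, hierarchical regression,
    bootstrap causal mediation, and trial-wise linear mixed-effects models
    with AIC comparison and per-subject slope extraction.
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
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
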