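Package: wptsim
Title: Weather Prediction Task Simulation, Scoring and Group Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and analyses probabilistic category learning
    experiments built on the weather prediction task (WPT).  Provides the
    task engine (cue cards, combination probabilities via the
    independent-cue odds product, balanced training/test/reactivation
    sequences), trial-log scoring with chance-corrected adjusted scores,
    an exact-binomial chance-level exclusion rule and key-reversal repair,
    prospective balanced (minimization-style) randomization of arriving
    participants, test-retest change statistics (one-sample and two-sample
    t, Cohen's d, one-way ANOVA with Fisher's LSD post hocs) rendered as a
    per-group summary table, and a synthetic-cohort generator so the whole
    pipeline can be exercised and calibrated without access to raw
    behavioral data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
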