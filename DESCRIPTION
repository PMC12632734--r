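Package: wmstates
Title: Population Spike-Train Analysis of Working-Memory On/Off States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of trial-structured multi-unit spike recordings from
    delayed-response working-memory tasks. Implements bias-corrected
    percentage-of-explained-variance (omega-squared) information time courses,
    leave-one-out lasso-logistic population decoding (8-way cross-temporal and
    binary diametric with posterior confidence), decoder-confidence on/off
    state labeling against label-shuffled nulls with cluster-mass correction,
    a population inter-spike-interval statistic for coordinated silent periods
    with trial-shuffle permutation inference, simultaneous versus
    pseudo-population decoding contrasts, beta-mixture modeling of decoder
    confidence, Welch spectra of state time series, and session-bootstrapped
    reaction-time/state effects. Includes a seeded synthetic spike-train
    generator (tuned Poisson populations, imposed silences, coordinated
    off-state gating, linked behavior) so every stage is testable without
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    arrow,
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
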