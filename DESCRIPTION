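Package: somnr
Title: Unsupervised Sleep Staging and Sleep-Quality Indices from
    Single-Channel EEG and Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores overnight single-channel EEG into a four-stage
    hypnogram (Wake, REM, Light, Deep) with an unsupervised hidden
    Markov model over wavelet band-power features, computes
    hypnogram-derived sleep-quality indices (REM-to-non-REM ratio,
    stage-shift index, sleep efficiency, total sleep time, sleep-onset
    latency, wake after sleep onset), scores wrist actigraphy counts
    into sleep/wake with the Sadeh regression, evaluates staging
    against reference hypnograms with per-stage one-vs-rest metrics,
    and compares sleep indices between intervention conditions with
    exact paired Wilcoxon tests and Spearman rank correlations.
    Includes a synthetic-data generator (hypnograms, band-limited EEG,
    actigraphy counts, whole cohorts) so the full pipeline is testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
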