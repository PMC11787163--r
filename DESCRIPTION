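Package: swaydyn
Title: Postural Sway Dynamics Under Cognitive Load and Auditory Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for force-plate center-of-pressure (CoP)
    posturography in dual-task experiments. Computes radial sway, its
    low/high-frequency Butterworth decomposition, and detrended fluctuation
    analysis (DFA) scaling exponents; fits random-intercept linear
    mixed-effects models with estimated marginal means and Tukey-adjusted
    pairwise contrasts across cognitive-load and auditory-noise conditions.
    Includes a synthetic cohort generator (anti-persistent fractional
    Brownian CoP sway with configurable condition effects) and a modified
    n-back letter task generator and scorer, so the full pipeline runs
    without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    ggplot2,
    signal,
    lme4,
    lmerTest,
    emmeans,
    yaml,
    jsonlite,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    pbkrtest
Config/testthat/edition: 3
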