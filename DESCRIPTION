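Package: plantmood
Title: Windowed Correlation of Plant Bioelectric Signals with Wearable Mood Readings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pairing raw plant surface-voltage recordings with sparse
    wearable mood readings and screening for within-day associations. Extracts
    twenty canonical features (statistical, temporal, spectral, shape) from the
    five-minute voltage window preceding each mood reading, builds ten mood
    variables (raw, composite, rolling), and runs a three-level correlation
    screen (pooled, within-day fixed effects via day-demeaning, and fixed
    effects with linear circadian detrending) with Benjamini-Hochberg and
    Bonferroni multiple-testing control. Includes electrode-era polarity
    diagnostics, lagged cross-correlation at shifted feature windows, and a
    synthetic-study generator with known ground truth (circadian drift,
    AR-correlated noise, era-dependent baselines and polarity, stress-coupled
    mean shifts and relative-variability suppression) for calibration and
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    optparse,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
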