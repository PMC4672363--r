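Package: eogbci
Title: Eye-Movement Classification and Game Control from Two Temporal EEG Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A streaming pipeline that detects and classifies six eye-movement
    classes (up, down, left, right, center, blink) from two temporal EEG
    electrodes sampled at 256 Hz, using the electrooculographic (EOG)
    component of the signal. Processing follows a real-time contract: causal
    Butterworth band-pass and notch filtering with state carried across 1-s
    blocks, decomposition into a low (0.5-10 Hz) EOG band, per-block baseline
    correction, derived horizontal (channel difference) and vertical (smoothed
    channel sum) signals, Haar continuous-wavelet scalogram event detection,
    and hierarchical fixed-threshold classification on four features (maximum
    wavelet coefficient, signed trapezoidal areas, amplitude, velocity).
    Decisions drive a two-dimensional obstacle-evasion game simulator with a
    velocity-vector control scheme. Includes a synthetic EOG/EEG generator
    emulating the 60-s trial protocol, threshold calibration, and evaluation
    tools (confusion matrices, precision/sensitivity/specificity, chance
    levels, command bit rates).
License: MIT + file LICENSE
Encoding: UTF-8
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
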