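Package: spindler
Title: Crowd-Consensus Sleep Spindle Annotation, Evaluation and Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building confidence-weighted group-consensus sleep spindle
    annotations from multi-scorer markings of N2 sleep EEG, for scoring human
    scorers and automated detectors by event-level overlap (intersection over
    union) matching with precision/recall/F1, for characterizing spindles per
    subject (density, duration, maximum peak-to-peak amplitude, dominant
    oscillation frequency), and for re-implementations of five classic automated
    sigma-band spindle detectors. Includes zero-phase Butterworth band-pass
    filtering and polyphase resampling of single-channel EEG, and a synthetic
    generator of artifact-free N2-like EEG blocks with injected spindle bursts
    and simulated scorer panels so the whole pipeline is testable end to end.
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
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
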