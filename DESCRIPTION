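Package: remcycle
Title: Probabilistic Modelling of Ultradian REM-Sleep Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the ultradian timing of REM sleep in rodent
    recordings. Implements a conditional lognormal Gaussian mixture model
    relating the duration of a REM episode to the amount of NREM sleep until
    the next REM episode, fitted per 30 s bin of preceding REM duration by
    expectation-maximization with logarithmic/linear parameter curves.
    Includes hypnogram I/O and sleep-cycle segmentation with microarousal
    scoring, Lilliefors-corrected Kolmogorov-Smirnov goodness-of-fit,
    sequential/single cycle taxonomy with refractory-period statistics,
    EEG spectral analysis (Welch densities, band powers, sleep-spindle
    detection), automatic sleep staging from EEG/EMG, bootstrap comparison
    of model parameters between conditions, and a synthetic-data generator
    producing ground-truth cycles, hypnograms and signals for validation.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
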