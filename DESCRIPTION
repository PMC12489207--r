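Package: dintest
Title: Simulated Digits-in-Noise Hearing Tests with Adaptive Staircases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for digits-in-noise (DIN) speech-in-noise hearing
    screening: transformed up-down (2-down/1-up) adaptive staircases with
    phase-scheduled step sizes, reversal counting and floor rules;
    SNR-exact stimulus assembly from digit and masker waveforms under a
    software calibration map; transcript normalization through a homophone
    dictionary and order-sensitive triplet scoring; stochastic virtual
    listeners and a recognizer-corruption model so whole test sessions and
    multi-run study designs can be simulated without audio hardware or
    participants; and an evaluation layer with speech-recognition error
    accounting, outlier exclusion, Bland-Altman agreement, Pearson
    correlation and RMSE.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
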