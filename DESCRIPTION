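Package: cogload
Title: EEG Cognitive-Load Analysis with Empirical Mode Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A subject-independent analysis pipeline for mental-arithmetic
    cognitive-load EEG. Decomposes 19-channel rest/task recordings into
    intrinsic mode functions by sifting with the standard-deviation stopping
    criterion, extracts per-mode statistical features (mean, SD, skewness,
    kurtosis, RMS, adjacent-band ratio), classifies rest versus task states
    with a polynomial-kernel support vector machine under several
    performance-grouped train/test designs, and summarises subject-level
    prediction tables. Includes channel-power scalp topography with a
    structural-similarity image comparison, a seedable synthetic rest/task
    cohort generator for end-to-end testing without data downloads, and
    minimal EDF (European Data Format) input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    FNN,
    quadprog,
    truncnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
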