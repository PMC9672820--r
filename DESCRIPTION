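Package: memdbci
Title: Masking Empirical Mode Decomposition and Backpropagation Networks
    for Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification pipeline for
    motor-imagery electroencephalography (EEG). Implements classical
    empirical mode decomposition (EMD) with cubic-spline envelopes,
    Hilbert spectral analysis (instantaneous amplitude and frequency),
    and masking EMD (MEMD), which suppresses mode mixing caused by
    intermittent oscillations by decomposing the signal plus and minus a
    data-driven sinusoidal mask and averaging the results. Per-IMF
    features (energy, morphological areas, fuzzy approximate entropy,
    autoregressive coefficients) feed a from-scratch feed-forward
    backpropagation neural network classifier. A seeded synthetic
    trial generator emulates class-dependent mu/beta band oscillations
    over autoregressive background noise so the whole pipeline is
    testable without external recordings.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
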