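Package: ftims
Title: Asynchronous Stepped-Frequency Fourier-Transform Ion Mobility
    Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for stepped- and swept-frequency
    Fourier-transform ion mobility spectrometry (FTIMS) on dual-gate drift
    tubes.  Builds stepped and chirped gate-modulation acquisition plans,
    simulates the two-gate steady-state correlation signal (including the
    long-rise-time current amplifier that makes asynchronous software
    triggering valid), deconvolutes interferograms into drift-time mobility
    spectra by FFT, fits peaks, and scores spectra with resolving power and
    signal-to-noise metrics.  Includes single-gate drift-tube simulation for
    method comparison, reduced-mobility calibration, frequency-parameter
    optimisation studies, and comparison-report arithmetic.
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
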