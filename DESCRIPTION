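Package: fractalEEG
Title: Fractal and Spectral Analysis of Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scale-free (fractal) analysis of multichannel
    resting-state EEG. Provides exact circulant-embedding simulation of
    fractional Gaussian noise and fractional Brownian motion, multiplicative
    binomial cascades, and a synthetic EEG cohort generator with configurable
    long-range temporal correlation, oscillatory band content and stereotyped
    artifacts; a preprocessing chain (equiripple FIR filtering, re-referencing,
    FastICA-based ocular artifact removal, band extraction, windowing);
    Welch power spectra, band powers and spectral entropy; generalized Hurst
    exponent estimation via q-order structure functions and multifractal
    detrended fluctuation analysis; a nonparametric statistical battery with
    multiple-comparison correction and k-fold validation; and group summaries
    with topographic scalp maps. Readers and writers for BrainVision and EDF
    recordings are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
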