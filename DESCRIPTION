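Package: dynfc
Title: Spatial and Temporal Dynamics of Functional Connectivity in Slow
    Hemodynamic and Multiband Electrophysiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing functional connectivity across recording
    modalities at mesoscale: band-specific decomposition of multichannel
    local field potential (LFP) signals into canonical frequency bands,
    Welch magnitude-squared coherence and band-limited power envelopes,
    elliptical-Gaussian point-spread-function fitting of activation and
    local-connectivity maps (FWHM and half-maximum ellipse area),
    sliding-window connectivity for slow hemodynamic-like series (Pearson
    correlation with Fisher z transform) and fast electrophysiological
    series (band-averaged coherence), discretization of windowed
    connectivity into putative brain states with jump-ECDF construction and
    two-sample Kolmogorov-Smirnov comparison, and Fourier decomposition of
    connectivity fluctuations into slow frequency bands.  A synthetic-data
    module generates electrode-grid recordings with calibrated
    distance-dependent coherence, Markov-switching coupled signal pairs
    shared between modalities, and block-design stimulus responses, so the
    full pipeline is testable end to end without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
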