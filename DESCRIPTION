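Package: wpconet
Title: Wavelet Phase Coherence Brain Networks from fNIRS Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resting-state functional-connectivity analysis for multichannel
    fNIRS oxyhemoglobin recordings. Implements hemodynamic preprocessing
    (canonical HRF low-pass smoothing and DCT high-pass detrending), complex
    Morlet continuous wavelet decomposition with time-averaged wavelet
    amplitude and instantaneous phase, pairwise wavelet phase coherence (WPCO)
    with amplitude-adjusted Fourier-transform (AAFT) surrogate significance
    testing, aggregation of channel-pair coherence into a 10-region prefrontal
    brain network, and the group-level statistics used to relate connectivity
    to behavioral performance (paired contrasts, extreme-group splits, Pearson
    correlation). A synthetic-cohort generator with planted cross-channel
    phase coupling provides a ground-truth test surface for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
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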