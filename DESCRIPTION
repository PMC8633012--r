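Package: ispct
Title: Significance Testing of Inter-Scale Wavelet Power Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte Carlo statistical significance testing of inter-frequency
    (inter-scale) power correlations in non-stationary time series. A signal
    is decomposed with a generalized Morse wavelet continuous wavelet
    transform, its wavelet power spectrum is filtered against the cone of
    influence, and the matrix of time-wise Pearson correlations between scale
    power series is tested against a two-element null: the mean inter-scale
    correlation induced by frequency-domain oversampling of the transform
    (estimated from white noise), plus the spread induced by intra-scale
    autocorrelation (estimated from phase-randomized surrogates of each
    scale). Multiplicity is controlled with the Cai-Liu false discovery rate
    procedure for dependent correlation statistics. Includes generators for a
    synthetic validation suite (sinusoids, pulses, chirps, square wave,
    exponential, white noise) and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
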