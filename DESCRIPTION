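Package: baroloop
Title: Closed-Loop Baroreflex Sensitivity from Beat-to-Beat Cardiovascular Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates closed-loop interactions between heart period (interbeat
    interval) and systolic blood pressure from beat-to-beat recordings.
    Implements uniform resampling of beat series, wavelet (MODWT) detrending
    with an adaptive dyadic cutoff, stationarity gating (ADF and KPSS),
    bivariate vector autoregressive modelling with AIC order selection and
    residual/stability diagnostics, parametric spectral factorization with
    zero-lag (instantaneous) interaction extraction, closed- and open-loop
    transfer functions, spectral and causal coherence, noise-source
    contributions, and band-level baroreflex sensitivity indices under four
    estimation strategies. Includes a ground-truth closed-loop simulator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
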