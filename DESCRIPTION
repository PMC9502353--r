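Package: pulsechain
Title: Pulse Rate Variability from Wrist-Worn Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processing chain that turns a raw wrist-worn photoplethysmogram
    (PPG) into a pulse-rate-variability (PRV) series and compares it against
    heart-rate variability (HRV) derived from a simultaneous ECG. Includes
    maximal-overlap discrete wavelet band filtering, amplitude demodulation
    (adaptive standardization, an online extrema-based method, and the
    analytic-envelope method), three systolic-peak detectors (PDA, AMPD,
    slope sum function) plus Pan-Tompkins R-peak detection, physiological
    and local-statistics interval screening, uniform resampling with
    zero-phase low-pass filtering, autoregressive sample correction, and
    evaluation metrics (dynamic time warping, aligned Pearson correlation,
    relative RMSE, Welch power spectral density). A seeded synthetic signal
    generator with integral-pulse-frequency-modulated beat trains and five
    laboratory artifact regimes provides ground truth for end-to-end tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
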