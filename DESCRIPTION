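Package: thermoresp
Title: Respiration Rate Estimation from Thermal Facial Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for contactless respiration-rate (RR)
    estimation from thermal facial video. A per-frame facial region of
    interest is detected and tracked (track-by-detection), the dynamically
    cropped video is temporally downsampled and windowed into clips, and a
    spatio-temporal estimator (temporal encoder-decoder 3D convolutional
    network followed by a bi-directional LSTM and a per-step linear head)
    regresses the 1-D respiratory waveform. Training uses a phase-tolerant
    objective combining the negative maximum band-limited cross-correlation
    (NMCC) with a saturating absolute peak-frequency difference (AFD), so
    that the chest-belt reference and the facial heat signal need not be
    phase aligned. RR is read out as the periodogram peak of the
    bandpass-filtered estimate. A synthetic thermal-recording generator with
    a known breathing frequency, belt phase lag, body sway and sensor noise
    makes every stage testable without access to restricted participant
    data. Grad-CAM heatmaps localize the spatial regions driving the
    estimate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
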