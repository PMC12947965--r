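Package: emgdi
Title: Detection of Inspiratory Onset and Offset in Surface Diaphragm EMG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for fully automatic detection of respiratory activity
    cycles and their onset/offset instants in long, ECG-contaminated
    surface diaphragm electromyography (EMGdi) recordings. Implements
    four ECG-suppression strategies (adaptive-threshold wavelet
    denoising, QRS gating, LMS adaptive cancellation with a
    self-synthesized cardiac reference, and their combination), moving
    RMS and fixed-sample-entropy envelopes with smoothing and
    exponential transformation, a dual moving-average cycle detector
    with kernel-density-estimated onset/offset thresholds, a
    simulation-calibrated timing-bias correction driven by the
    inspiratory-to-basal signal-to-noise ratio, and event/timing
    agreement metrics against double-scorer expert annotations. A
    synthetic-signal generator with known ground-truth cycle timing
    supports end-to-end validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    minpack.lm,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
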