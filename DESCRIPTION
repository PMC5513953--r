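Package: dusqi
Title: Template-Based Signal Quality Assessment for 1-D Doppler Ultrasound
    Fetal Heart Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality assessment pipeline for one-dimensional Doppler
    ultrasound (DUS) recordings of the fetal heart. Detects cardiac cycles
    with empirical mode decomposition and continuous-wavelet envelopes,
    builds running per-window beat templates, and scores every beat with
    four template-correlation signal quality indices (direct, linearly
    resampled, dynamic-time-warped and phase-weighted DTW matching).
    Segment-level features (median SQIs, sample entropy, Doppler-band
    power-spectral-density ratio) feed a radial-basis-function support
    vector machine that labels 3.75-second segments as good or poor
    quality, validated with subject-stratified bootstrap cross-validation.
    A seeded synthetic-recording generator with known beat times and
    per-second quality labels makes every stage testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
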