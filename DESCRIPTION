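Package: heartseg
Title: Automated Time-Label Segmentation of Heart Sound Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for segmenting phonocardiograms (PCG) into the four
    acoustic states of the cardiac cycle (first heart sound S1, systole,
    second heart sound S2, diastole). Detection runs on a normalized
    average Shannon-energy envelope: S1 peaks are found as the dominant
    quasi-periodic peak train, S2 as the strongest interior envelope peak
    between adjacent S1s with robust outlier rejection, and segment
    boundaries by fractional-height/valley localization. Labels are
    exchanged as Audacity label tracks. A per-segment feature battery
    covers durations, frame-level dBFS amplitude statistics, waveform
    shape statistics, autocorrelation-based fundamental-frequency and
    periodicity measures (jitter, harmonics-to-noise ratio, harmonic
    ratio), plus heart-rate estimation and paired-t cross-validation
    against a reference pulse monitor. A parametric synthetic PCG
    generator with exact ground-truth labels makes the whole chain
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    signal,
    tools,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
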