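Package: sonomuscle
Title: Transverse Muscle Oscillations from B-Mode Ultrasound During Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies in vivo transverse oscillations of muscle tissue from
    B-mode ultrasound image sequences recorded during walking and running.
    Provides an active-shape-model segmentation of aponeurosis landmarks
    (point distribution model plus multi-resolution intensity-profile search),
    spectral statistics of landmark transverse displacement (stride-frequency
    high-pass, 0-40 Hz power spectra, peak power and 50% cumulative
    frequency), ground-reaction-force impact input-frequency estimation,
    EMG intensity via a bank of non-linearly scaled wavelets, repeated-measures
    statistics, and a synthetic-data generator with known ground truth that
    drives the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tiff,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
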