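Package: rdppg
Title: PPG/ECG Beat Quality Screening with a Reaction-Diffusion Template
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quality screening of photoplethysmography (PPG) and
    electrocardiography (ECG) recordings by template matching. A two-cell
    nonlinear reaction-diffusion oscillator (realisable as a State-Controlled
    Cellular Neural Network) generates a reference pulse waveform; segmented,
    equiripple-FIR pre-filtered PPG beats are scored against it by lagged
    normalised cross-correlation and accepted at a 0.90 compliance threshold.
    Accepted beats' first derivatives then validate simultaneously recorded
    ECG beats through a dual cross-correlation AND gate at 0.80. Medical
    indicators (heart rate, heart-rate variability, augmentation index, pulse
    transit time and pulse wave velocity) are computed from the clean beat
    sets. Includes a seeded synthetic generator of paired PPG+ECG records
    with per-beat ground-truth quality labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
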