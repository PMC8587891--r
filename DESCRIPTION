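Package: ecgnorm
Title: Heart-Rate-Aware Non-Linear ECG Beat Normalization and Biometric
    Verification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for electrocardiogram (ECG) based biometric
    authentication under varying heart rates. Implements wavelet-based
    denoising and fiducial-point delineation of single-lead ECG,
    per-section regression of beat-section durations against heart rate,
    non-linear beat normalization that resamples each of the four beat
    sections (PR interval, QRS complex, ST interval, TP segment) to its
    expected duration at a 70 bpm reference heart rate, template building
    with correlation-based outlier rejection, extraction of 29 fiducial
    features, Relief-F feature weighting, and one-vs-rest verification
    with FAR/FRR/EER evaluation. Includes a synthetic multi-subject ECG
    generator with ground-truth fiducials for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    rpart,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
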