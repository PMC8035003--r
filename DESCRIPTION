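Package: tsaprv
Title: Pulse Rate Variability and Atrial Fibrillation Detection by Improved
    Time Synchronous Averaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures pulse rate variability (PRV) from single-channel radial
    artery pulse wave recordings by an improved time synchronous averaging
    (TSA) procedure in which two adjacent pulse periods form the averaging
    unit.  Beat-to-beat irregularity smears the second period of the averaged
    waveform, and the distance between the first and second ascending limbs
    (Euclidean, Manhattan, cosine) quantifies PRV without ever estimating an
    inter-beat-interval series.  The Euclidean limb distance is used to
    detect atrial fibrillation.  Includes derivative-threshold beat
    segmentation with automatic threshold selection and rule-based segment
    quality screening, a seeded simulator of pulse recordings with
    prescribed cycle-duration jitter (for index screening on a synthetic
    training set), and ROC/AUC plus Kruskal-Wallis evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
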