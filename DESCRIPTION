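Package: ecgkit
Title: Four-Stage Arrhythmia Discrimination from Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated discrimination of arrhythmic episodes in single-lead
    electrocardiogram (ECG) recordings through a four-stage cascade:
    ventricular fibrillation detection from image-based phase-plot, spectral
    and entropy features of 8 s segments; atrial fibrillation detection from
    RR-interval statistics (Shannon entropy, turning point ratio, RMSSD);
    premature ventricular contraction (PVC) beat detection from time,
    frequency and nonlinear beat features; and rule-based classification of
    PVC occurrence patterns (bigeminy, trigeminy, quadrigeminy, couplet,
    triplet, ventricular tachycardia). Includes preprocessing for WFDB and
    CSV records, binary decision tree and linear SVM evaluation protocols
    with balanced and unbalanced splits, and a synthetic ECG generator for
    fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
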