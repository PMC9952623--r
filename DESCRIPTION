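Package: ctgsuite
Title: Analysis and Classification of Cardiotocographic Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for computerized analysis of cardiotocographic (CTG)
    recordings: signal quality screening and gap interpolation, baseline and
    floating-line estimation, FIGO-style acceleration/deceleration detection,
    tachycardia/bradycardia recognition, short-term variability (STV) of the
    fetal heart rate variability signal, short-time Fourier transform spectral
    band powers and the sympatho-vagal balance (LF/HF), rule-based annotation
    of suspicious traces via a six-bit alarm mask, and support vector machine
    classification with k-fold cross-validation and a full confusion-matrix
    metric suite (sensitivity, specificity, precision, F-beta, G-mean, with
    arithmetic and class-size-weighted aggregation). A seeded synthetic CTG
    generator with ground truth supports end-to-end validation without access
    to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
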