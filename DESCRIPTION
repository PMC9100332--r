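Package: ecgscope
Title: Scope-Flexible ECG Biometric Identification with Sequence-Pair Self-Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Electrocardiogram (ECG) biometric identification and verification built on a
    sequence-pair feature extractor with self-attention. Raw single-lead ECG is blindly
    segmented into 3 s windows (no fiducial points), bandpass filtered and standardized;
    each enrolled/query segment pair is encoded jointly by a transformer encoder with
    classification tokens, and a second, permutation-equivariant encoder over the enrolled
    scope turns pairwise features into a closed identification distribution, so the
    enrollment scope can grow or shrink without retraining. Includes a synthetic
    multi-identity ECG generator with heart-rate variability, noise, baseline wander and
    slow morphology drift; a multi-database example generator for training; an Adam
    training loop with label smoothing and early stopping; segment voting over long
    enrollments; and an ROC/EER evaluation protocol under configurable time separation
    between enrollment and classification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
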