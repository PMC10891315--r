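Package: sptask
Title: Task-State Skin Potential Analysis for Mood-Disorder Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of task-state skin potential (SP)
    recordings, an electrodermal signal sampled at 5 Hz during
    emotion-inducing tasks. Implements signal preprocessing (Hampel
    outlier removal, gap interpolation, zero-phase low-pass filtering,
    wavelet denoising, per-task min-max normalization), extraction of 18
    time- and time-frequency-domain features per task (including eight
    0.0625 Hz wavelet-packet band energies over 0-0.5 Hz), per-feature
    one-way ANOVA with Bonferroni or Tamhane T2 post hoc comparisons,
    balanced-subsample RBF-SVM discrimination of bipolar depression,
    major depressive disorder and healthy controls under leave-one-out
    cross-validation with a full confusion-matrix metric suite, and
    correlation screening of SP features against blood oxidative-stress
    markers. A synthetic cohort generator with controllable band-energy
    profiles, drift, artifacts and planted feature-marker correlations
    makes every stage testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    MASS,
    class,
    nnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
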