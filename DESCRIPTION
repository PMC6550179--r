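Package: gaitrisk
Title: Accelerometer-Based Gait Features and Fall-Risk Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates hip-worn 30 Hz triaxial accelerometer tracings of
    400-m walk tests for older-adult cohorts with controllable gait
    parameters, extracts steady ("good") walking segments from raw
    tracings by sliding-window segmentation, an inactivity filter on
    vector-magnitude variability and a periodicity-based walking mask,
    computes a battery of time- and frequency-domain signal features
    together with traditional gait measures (cadence, step and stride
    timing), and classifies subjects into high versus low fall-risk
    groups with random forests under 10-fold cross-validation, including
    entropy-based mean-decrease-impurity feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ranger,
    rpart,
    e1071,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
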