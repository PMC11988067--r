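Package: grazeclass
Title: Cattle Behavior Classification from GPS-Accelerometer Collar Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for classifying free-ranging cattle behavior
    (grazing, walking, drinking, resting, ruminating, and posture) from
    5-minute GPS fixes coupled with triaxial accelerometer activity counts.
    Includes a semi-Markov bout simulator for behavior-annotated collar data,
    GPS fix cleaning (satellite, altitude, interval and paddock-buffer rules),
    movement metrics (distance, speed, bearing, straightness index),
    accelerometer features (Actindex, ODBA, VEDBA, pitch, roll, energy
    expenditure), behavior labeling with a 3-minute bout rule, random-forest
    importance plus correlation-filter feature selection, and evaluation of
    six classifier families under random train-test split and k-fold
    cross-validation with per-class metrics and partial-dependence curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    nnet,
    e1071,
    caret,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
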