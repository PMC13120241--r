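Package: odourfusion
Title: Odour-Image Multimodal Fruit-Ripeness Analysis with Temperature-Modulated Gas Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal processing, feature extraction and classifier evaluation for
    temperature-modulated metal-oxide (MOX) gas-sensor arrays used in open-air
    fruit-ripeness monitoring, together with late decision fusion of the odour
    modality with camera-based detections. Provides per-modulation-level
    segmentation of heater-voltage acquisition patterns, EWMA response-curve
    features, radial-basis-function humidity/temperature response correction,
    a native extreme learning machine alongside standard classifiers under
    stratified, leave-k-day-out and 24-hour-group cross-validation, reduction
    of object-detection outputs to image-level labels via confidence filtering
    and non-maximum suppression, maximum-confidence and majority-vote fusion
    with agreement analysis, and a seeded synthetic-data generator emulating
    the acquisition protocols so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    randomForest,
    xgboost,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
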