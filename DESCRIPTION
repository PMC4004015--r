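Package: harwear
Title: Activity Recognition from Smartphone and Smartwatch Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for human activity recognition from multi-rate
    smartphone and smartwatch sensor recordings. Provides a seeded generator
    of physically plausible multi-sensor sessions (tri-axial accelerometer,
    magnetometer, gyroscope, barometric pressure, ambient light and GPS) with
    ground-truth activity annotations; linear resampling of irregular streams
    to fixed rates with hold-last-value gap filling; a zero-phase Butterworth
    filter bank separating gravity from gait-band dynamics and detrending
    pressure; fixed two-second windowing of annotated segments; a 53-attribute
    phone feature set and a 17-attribute watch subset (actigraphy counts,
    device angles, spectral peaks, step counts, displacement and barometric
    altitude features); GPS and light features for indoor/outdoor detection;
    balanced and unbalanced dataset assembly with CSV and ARFF interchange;
    and stratified cross-validated evaluation of five classifiers with
    optional PCA reduction at a target explained variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    foreign,
    rpart,
    nnet,
    e1071,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
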