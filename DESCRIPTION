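Package: actirest
Title: Rest Period Detection and Cluster-Based Rest Quality from Wearable
    Patch Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Detects each patient-day's longest rest period from per-minute
    accelerometer summaries recorded by a digital medicine system (DMS) patch,
    quantifies the relative quality of rest inside that period with a
    per-patient k-means rest-reference model and Euclidean distance metric,
    standardizes daily rest quality, start time and duration into z-scores and
    a composite rest score, and relates single-day rest outliers to
    time-stamped medication ingestion records.  Ships a synthetic
    patient-stream simulator with ground-truth rest schedules, missing spans
    and dose-time variability so every stage of the pipeline can be validated
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
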