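Package: choiq
Title: Channelised Hotelling Observer Assessment of CT Low-Contrast Detectability
Version: 0.1.0
Authors@R: person("IQ", "Lab", email = "iqlab@example.org", role = c("aut", "cre"))
Description: Task-based image-quality analysis for CT phantom acquisitions.
    Implements a channelised Hotelling observer with dense difference-of-Gaussian
    channels, nonparametric ROC/AUC estimation with bootstrap uncertainty, a
    synthetic phantom-image generator for validation, reading of classic
    single-frame CT DICOM series with ROI extraction at configured lesion
    positions, and multicentre aggregation statistics (distribution summaries,
    Pearson correlation matrices with qualitative strength labels).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
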