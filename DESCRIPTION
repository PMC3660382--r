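Package: eustex
Title: Texture-Based Computer-Aided Differentiation of Pancreatic
    Lesions on Endoscopic Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computer-aided differentiation of pancreatic cancer from
    chronic pancreatitis on endoscopic-ultrasound (EUS) still images.
    Extracts a canonical 105-feature, 9-category texture description
    (grey-level histogram, co-occurrence, run-length and difference
    statistics, wavelet subband statistics, Laws masks, gradient
    statistics) from rectangular sub-images of manually delineated
    regions of interest, selects features by a robust class-distance
    ranking followed by sequential forward selection scored by the
    support-vector-machine correct-classification rate, and validates
    the classifier with repeated stratified half-and-half splits and
    leave-one-out cross-validation, reporting accuracy, sensitivity,
    specificity and predictive values. A seeded speckle-texture
    simulator generates two-class ultrasound-like cohorts so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
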