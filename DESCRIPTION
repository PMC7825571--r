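Package: mothtrap
Title: Detection, Tracking, Classification and Counting of Moths in
    Light-Trap Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for camera-based light traps that
    monitor nocturnal insects. Frames recorded against a uniform bright
    sheet are segmented by background subtraction and Otsu thresholding,
    individual insects are tracked across frames by Hungarian assignment
    on a weighted distance/area cost, each track is classified with a
    compact convolutional neural network trained on small augmented
    datasets, and per-survey species counts are derived by track-level
    majority vote. Includes tracking and classification quality metrics
    (tracking detection rate, false alarm rate, per-class precision,
    recall and F1), a synthetic scene and crop generator with ground
    truth for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
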