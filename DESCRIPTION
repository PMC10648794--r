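Package: kcscreen
Title: Whole-Slide Image Screening for Odontogenic Keratocysts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying whole-slide histopathology
    images as odontogenic keratocyst (OKC) versus non-keratocyst. Slides are
    partitioned into fixed-size tiles, white and uninformative tiles are
    discarded with an Otsu-threshold tissue filter, and the remaining tiles are
    classified by a compact convolutional network whose flattened features are
    reduced by principal component analysis and ranked by a ReliefF feature
    selector before a small two-layer dense head. Per-tile probabilities are
    aggregated into a slide-level call by thresholding the fraction of
    OKC-predicted tiles. Includes a synthetic slide generator with known
    per-tile ground truth, a full evaluation-metric suite, and plotting and
    broom-style tidier methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
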