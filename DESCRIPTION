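Package: earcount
Title: Occlusion-Aware Augmentation and Counting Evaluation for Wheat Ear
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for building and evaluating occlusion-robust wheat ear
    counting pipelines. Provides a density-guided occlusion-simulation
    augmentation (Random-Cutout) together with the classical Cutout and
    Random Erasing baselines, a numeric reference implementation of the
    convolutional block attention module (CBAM), detection post-processing
    (confidence filtering and greedy non-maximum suppression), counting
    evaluation metrics (counting accuracy, false detection rate, frames
    per second), readers and writers for common bounding-box annotation
    dialects, and a deterministic generator of synthetic annotated wheat
    ear scenes for testing without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    optparse,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
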