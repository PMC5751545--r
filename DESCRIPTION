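Package: ncproj
Title: Network Consistency Projection for Microbe-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores every disease-microbe pair in a sparse binary bipartite
    association network by combining Gaussian interaction profile (GIP) kernel
    similarity with network consistency projection. Includes the three standard
    evaluation frameworks for bipartite link prediction (global leave-one-out
    cross-validation, local leave-one-out cross-validation, and repeated k-fold
    cross-validation with rank-based ROC/AUC), a planted-block synthetic network
    generator for end-to-end testing without external data, tidy accessors for
    every result type, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    tibble,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
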