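Package: palmleaf
Title: Leaf Area Estimation for Palmate Leaves by Cluster-Based
    Photography and Allometric Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for measuring and estimating the leaf area of palmate
    (cassava-type) leaves.  Implements silhouette segmentation and
    calibrated area/length/width measurement from white-background leaf
    photographs, size clustering on a scoring-board grid with
    representative sampling and per-plant total leaf area aggregation,
    through-origin allometric models on length-width predictors with
    screening and model selection, evaluation metrics (RMSE, MAE, mean
    relative error, Pearson correlation) for comparing per-plant totals
    between methods, and a synthetic palmate-leaf generator providing
    resolution-independent ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
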