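Package: vesseltort
Title: Retinal Vessel Tortuosity Metrics and Severity Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the tortuosity of retinal blood vessels from binary
    vessel-segmentation masks. Extracts a one-pixel-wide centerline skeleton by
    iterative thinning, prunes spurs, separates the vasculature into ordered
    vessel segments at branch points, and computes fourteen segment-level
    tortuosity metrics (arc and chord length, distance metric, distance factor,
    tortuosity density, curvature integrals, sum-of-angles metric, inflection
    count metric) together with signed-curvature summaries. Segment records are
    aggregated into per-image feature tables which, joined with ordinal severity
    labels (normal, mild, moderate, severe), train decision-tree, rotation-forest
    and random-forest graders evaluated by stratified cross-validation (accuracy,
    Cohen's kappa, confusion matrix, RMSE, MAE, per-class ROC-AUC). A seeded
    synthetic vasculature generator provides analytic ground-truth curves and
    labeled datasets for testing the full pipeline.
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
    igraph,
    pracma,
    purrr,
    png,
    pROC,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
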