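Package: berryripe
Title: Fine-Grained Strawberry Ripeness Grading from Instance Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for grading strawberry ripeness into six ordinal stages
    (White to Full ripe) from RGB images with per-instance segmentation
    masks. Implements a geometric partition of each fruit mask into four
    ordered sub-regions cut perpendicular to the longest chord through the
    mask centroid, regional colour-feature extraction in selected RGB, HSV
    and CIELAB channels, classical multi-class classifiers (logistic
    regression, k-nearest neighbours, random forest, support vector
    machine) with stratified cross-validated grid search, a standalone
    self-calibrated convolution forward pass, and a seeded synthetic-fruit
    generator so the whole pipeline is testable without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    EBImage,
    e1071,
    ranger,
    caret,
    glmnet,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
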