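Package: nutrimap
Title: Nutrient-Value-Based Food Grouping for Food Composition Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for grouping foods by their nutrient
    composition. Reads food-composition tables with missing entries,
    imputes missing nutrient values by combining a pairwise-available-case
    distance, classical multidimensional scaling and random-forest
    regression, converts composition per 100 g to nutrient density per
    100 kcal, maps foods in two dimensions with t-SNE, and classifies
    foods into groups with k-nearest neighbours, reporting confusion
    matrices and misclassification rates. Includes a synthetic
    food-composition generator with group-structured profiles,
    Atwater-consistent energy and block missingness for testing every
    stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ranger,
    Rtsne,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    class,
    readxl,
    withr
Config/testthat/edition: 3
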