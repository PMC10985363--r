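Package: nicheshift
Title: Niche-Shift Quantification and Ensemble Distribution Models for
    Invasive Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies climatic niche shifts between the native and invaded
    ranges of a species and models its potential distribution. Implements the
    environmental-space (PCA-env) occupancy-grid framework: accessible-area
    backgrounds from buffered minimum convex polygons, kernel-smoothed
    occurrence and availability densities on a principal-component grid,
    Schoener's D overlap, a niche-similarity permutation test, and the
    expansion/stability/unfilling decomposition restricted to analog climates.
    Also provides an ensemble species-distribution pipeline with
    principal-component predictors, environmentally constrained
    pseudo-absences, spatial block cross-validation, four model algorithms,
    Jaccard evaluation, a Jaccard-weighted ensemble, and an a-posteriori
    occurrence-based spatial constraint. A virtual-species simulator generates
    spatially autocorrelated climate stacks and paired occurrence sets with
    analytically known shift structure, so the whole workflow is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    geosphere,
    glmnet,
    e1071,
    randomForest,
    xgboost,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
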