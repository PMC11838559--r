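Package: wmogradients
Title: Cortical Gradient and Representational Similarity Metrics of
    Working-Memory Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline from parcellated multivoxel activation patterns
    to individual-difference statistics for instructed working-memory control
    operations (maintain, replace, suppress, clear). Implements operation-wise
    and windowed resting-state representational similarity analysis,
    operation-weighted task functional connectivity, diffusion-map cortical
    gradients with Procrustes alignment, network eccentricity and Mahalanobis
    within-network dispersion, one-vs-other MVPA decoding accuracy, and staged
    hierarchical regressions (with FDR, nested F-tests and VIF) predicting a
    composite thought-control-difficulties score. Includes a synthetic-cohort
    generator with known ground-truth couplings for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    pROC,
    car
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
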