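Package: netbrainage
Title: Brain Age Prediction, Network Lesion Importance, and Transcriptomic
    Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts chronological age from regional gray-matter volumes with
    Gaussian process regression under repeated k-fold cross-validation,
    quantifies the contribution of each brain network by computational lesion
    analysis scored with Steiger's Z test for dependent correlations, and
    annotates the decisive network with gene-expression associations derived
    from spatially localized expression samples (sphere-ROI mapping, per-donor
    median normalization, permutation testing with family-wise error control)
    followed by hypergeometric over-representation analysis of the resulting
    gene list. Includes synthetic-data generators (atlas parcellations, aging
    cohorts, multi-donor expression datasets, gene-set collections) with known
    ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
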