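Package: dipr
Title: Differentially Penalized Regression for Trait Prediction from
    Markers and Metabolites
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts quantitative traits from two heterogeneous sets of
    covariates (for example genome-wide presence/absence markers and
    metabolite profiles) with differentially penalized ridge regression
    (DiPR): each covariate block receives its own shrinkage penalty,
    realized by rescaling the blocks with weights w and 1-w and fitting a
    single-penalty ridge, with the weight and penalty chosen by
    leave-one-out cross-validation on a grid.  Includes marker quality
    control (minor-allele-frequency filtering and correlation-based
    deduplication), training-fold standardization, an exact fast
    leave-one-out evaluator, the nested drop-one cross-validation
    protocol for honest accuracy estimates, Mantel tests between
    block-wise distance matrices, and a seeded synthetic-data generator
    that emulates the marker/metabolite/trait structure of a wheat
    diversity panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse,
    jsonlite
Config/testthat/edition: 3
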