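Package: beerich
Title: Taxon and Land-Cover Indicators of Wild-Bee Species Richness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds indicators of wild-bee species richness on a 3x3 km grid
    from land-cover composition and effort-corrected bird abundance.
    Standardizes bee occurrence records into per-cell richness, corrects
    bird checklist counts for survey effort with generalized additive
    models, screens and selects predictors with a best-subset regression
    ensemble (100 sub-models of at most 10 predictors ranked by an
    information criterion), validates predictor sets by five-fold
    cross-validation and dependent-correlation tests, and emits prediction
    and scaled-uncertainty surfaces. A synthetic-data module generates
    landscapes, bird checklists and bee surveys with known ground truth so
    the full pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
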