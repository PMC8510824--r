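Package: cfnforest
Title: Cascade Flexible Neural Forests for Expression-Based Subtype Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Multi-class classification of high-dimensional, small-sample gene
    expression matrices with cascades of flexible neural tree (FNT) ensembles.
    Tree structures are evolved by grammar-guided genetic programming and their
    weights fitted by particle swarm optimization; an M-ary binary decomposition
    turns the multi-class problem into per-bit regression targets, bagged FNT
    groups form forests, and forests with diverse function sets are stacked in a
    cascade with feature augmentation, confidence-gated early exit and weighted
    layer fusion. Includes expression-matrix preprocessing (missing-sample
    filtering, KNN imputation, per-gene standardization), a synthetic
    class-conditional expression data generator, and stratified cross-validation
    with macro precision/recall/F1 reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
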