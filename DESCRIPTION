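Package: ruleforest
Title: Sparse Regression Rule Ensembles from Regularized Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns small, human-readable sets of regression rules from
    random forests. Every root-to-leaf path of a regression forest is
    treated as an IF-THEN rule; samples are encoded into the resulting rule
    space and a 1-norm-regularized linear program, solved by a built-in
    interior-point solver, selects a sparse subset of rule weights.
    Features absent from the surviving rules are eliminated and the forest
    is regrown iteratively until the selected feature set stabilizes.
    Includes the evaluation protocol for accuracy (R-squared),
    interpretability (rule and feature counts) and robustness to injected
    feature noise, plus synthetic benchmark generators with known ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    randomForest,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
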