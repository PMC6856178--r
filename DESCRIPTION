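Package: motiliflow
Title: Sperm Motility Prediction from Microscopy Video Representations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computer-assisted sperm analysis toolkit that predicts the
    percentages of progressive, non-progressive and immotile spermatozoa
    from microscopy videos of semen samples. Implements four video-to-image
    representations (greyscale channel stacks, vertical frame matrices,
    sparse Lucas-Kanade trajectory images and dense Farneback optical-flow
    images), Tamura texture features for a classical regression baseline,
    convolutional regressors with an optional participant-data fusion head
    and two-stream variants, grouped three-fold cross-validation with mean
    absolute error reporting, and the variance-corrected paired t-test for
    comparing methods against a ZeroR null model. A synthetic sperm-video
    simulator with exact ground-truth motility fractions makes the whole
    pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    Rcpp,
    randomForest,
    e1071,
    kernlab,
    glmnet,
    rpart
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
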