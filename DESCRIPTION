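Package: FishFlow
Title: Trajectory-Image Analysis and Classification of Fish Escape Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An assistive computer-vision pipeline for behavioral assays of a
    single fish swimming in a circular arena. Videos are converted into a
    single "trajectory image" by per-frame fish detection (temporal-median
    background subtraction), circular masking, dense optical flow between
    consecutive masked frames and per-pixel fusion. Trajectory images are
    compressed to low-dimensional feature vectors with an autoencoder, scarce
    training data are enlarged by sampling class-conditional Gaussian mixture
    models, and a binary behavioral-change verdict is produced by standard
    classifiers. Includes a synthetic arena-video generator with ground-truth
    boxes, a PASCAL-VOC-style mAP@IoU detector evaluator and a repeated
    random-subsampling cross-validation protocol with accuracy, precision,
    recall and F1 reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    png,
    jsonlite,
    e1071,
    rpart,
    randomForest,
    glmnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
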