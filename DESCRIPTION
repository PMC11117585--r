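Package: dccnn
Title: Decorrelated Convolutional Neural Networks for Bias-Invariant
    Neuroimage Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits small convolutional neural networks whose training
    objective carries a distance-correlation (dCor) penalty between learned
    features and a per-sample bias variable, yielding features invariant to
    class imbalance or to scanner/acquisition differences in grayscale
    slice-image cohorts. Provides exact and sample-weighted squared distance
    correlation with analytic feature gradients, dummy class-bias, voxel-size,
    scanner-classifier and temporal-fluctuation bias variables, oversampling
    and weighted-loss baselines (ROS, SMOTE, stratified sampling, inverse
    frequency class weights), a convolutional GRU front end for temporal
    stacks, slice-to-subject max-wins voting, scanner-probe bias audits,
    ROC/confusion metrics, a seeded synthetic multi-scanner phantom generator,
    and PNG/NIfTI manifest-based IO.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    yaml,
    jsonlite,
    glmnet,
    EBImage,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    RNifti,
    optparse
Config/testthat/edition: 3
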