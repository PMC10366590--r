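Package: broadvol
Title: Deep-Broad Ensemble Classification of 3D Volumetric Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A deep-broad ensemble classifier for 3D volumetric images such
    as structural brain MRI. A fixed, never-trained random-weight 3D residual
    convolutional network (stem convolution-pooling followed by two bottleneck
    residual modules) extracts a 256-dimensional shallow and a 512-dimensional
    deep feature vector per volume; a Broad Learning System maps these through
    random feature and enhancement nodes and learns only its output weights in
    closed form by the ridge-regression pseudo-inverse, so no backpropagation
    is required. Includes NIfTI preprocessing (isotropic resampling, intensity
    normalisation, center cropping), a deterministic synthetic phantom
    generator for end-to-end testing without clinical data, stratified
    subject-level evaluation with standard classification metrics and ROC
    curves, a hyperparameter stability sweep, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    caret,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
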