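Package: dlradiomics
Title: Deep-Learning-Based Radiomics for MR Tumor Phenotype Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end deep-learning-based radiomics (DLR) for multi-modal
    brain MR volumes. A patch-based convolutional network segments the tumor
    pixel-wise; scalar responses of its last convolutional layer, pooled over
    multi-scale tumor regions of interest, are encoded into a fixed-length
    improved Fisher vector under a shared scalar Gaussian mixture; filtered
    (two-sample t-test) and F-score-ranked descriptor dimensions feed a linear
    support-vector classifier evaluated by leave-one-out cross-validation or a
    diagnosis-time split. Includes a phantom generator with phenotype-dependent
    tumor texture so the whole pipeline is exercisable without clinical data,
    NIfTI/CSV input-output, and a staged command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
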