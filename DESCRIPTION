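Package: viewfuse
Title: Class-Selective Fusion of Two-View Linear SVM Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-level fusion of two linear support vector machine
    classifiers trained on complementary feature views of the same samples,
    aimed at imbalanced binary classification of histopathology images
    (presence versus absence of epithelial dysplasia). One view is expected
    to discriminate the presence class well, the other the absence class;
    an explicit four-rule class-selection algorithm merges the two
    calibrated classifier outputs. Includes manifest and feature-view I/O,
    a deterministic image-statistics feature backend, a synthetic two-view
    data generator with controlled class imbalance and per-view asymmetric
    separability, stratified k-fold cross-validation, and the evaluation
    suite (balanced accuracy, sensitivity, specificity, precision, ROC AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
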