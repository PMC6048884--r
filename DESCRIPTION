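Package: micronodule
Title: Discriminating Pulmonary Micro-Nodules from Non-Nodules in CT with Small CNNs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: False-positive reduction for pulmonary micro-nodules (diameter
    < 3 mm) in low-dose CT. Parses LIDC/IDRI-dialect annotation XML into typed
    lesion marks, loads CT DICOM series, extracts normalized square image
    patches (16, 32 or 64 pixels) centred on each micro-nodule or non-nodule
    mark, and trains three small convolutional neural networks of differing
    depth (1, 2 or 4 convolutional layers) with stochastic gradient descent
    and momentum. Classifiers are evaluated under stratified fivefold
    cross-validation with macro F-score, accuracy, sensitivity and the area
    under the ROC curve. Includes a synthetic fixture generator emulating both
    the annotation dialect and labelled patch datasets with controllable class
    separability, so the full pipeline is testable without the archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
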