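Package: mammotriage
Title: Triage of Special Diagnostic Mammography Views from DICOM Headers and Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies special diagnostic mammography views (spot compression,
    magnification, stereotactic, specimen and wire-localization images) so they
    can be removed before assembling large full-field mammogram training sets.
    Combines a gradient-boosted classifier on engineered DICOM header features
    with an abridged Inception-style image classifier and a dedicated
    wire-localization detector, fuses their probability scores with fixed
    max/mean rules, and selects a sensitivity-targeted operating threshold.
    Includes a synthetic DICOM phantom generator so the whole pipeline is
    exercisable without any clinical data, plus from-scratch evaluation
    statistics: auROC with DeLong variance and paired test, average precision,
    and the exact McNemar test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
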