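Package: blockmvpa
Title: Multivariate Pattern Analysis and Individual-Difference Prediction
    for Block-Design fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for decoding task states and predicting individual
    differences from block-design functional MRI. Simulates multi-subject
    BOLD studies with plantable multivoxel condition effects and behavioral
    score encodings; estimates block-wise response patterns with a robust
    weighted least-squares general linear model; performs motion and
    behavioral quality control (framewise displacement, DVARS, density-based
    outlier flagging); runs searchlight and region-of-interest decoding with
    linear support vector machines; predicts behavioral scores with
    leave-one-participant-out and cross-sample nu-support-vector regression;
    and assesses everything with permutation-based inference and false
    discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    signal,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
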