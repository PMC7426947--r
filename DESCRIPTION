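Package: hipfrax
Title: Auxiliary-Text Training for Hip-Fracture Radiograph Classification
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a multimodal training framework in which an image
    encoder's 64-dimensional latent code is simultaneously decoded into the
    paired radiology report (bidirectional LSTM decoder) and classified into
    AO/OTA proximal-femur fracture classes (normal, A1-A3, B1-B3), so that an
    image-only classifier at test time benefits from report text seen only
    during training. Provides the three training regimes (image-only baseline,
    two-stage M1, jointly trained M2), focal loss for class imbalance,
    Grad-CAM class-discriminative saliency, hierarchical 2/3/7-class
    evaluation, a GloVe-style co-occurrence word-embedding fit, and a
    synthetic paired radiograph-phantom/report generator standing in for
    protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
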