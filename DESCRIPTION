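Package: lungpaste
Title: Anatomy-Aware Paste Augmentation and One-Class Anomaly Detection
    for Chest Radiographs
Version: 0.1.0
Authors@R:
    person("Lungpaste", "Developers", email = "lungpaste@example.org",
           role = c("aut", "cre"))
Description: Unsupervised anomaly detection for chest radiographs built on a
    self-supervised pretext task. Provides annotation-free lung-field
    segmentation (CLAHE, Otsu binarization, morphology, border clearing,
    component-size filtering), an anatomy-aware cut-paste augmentation that
    synthesizes lung-confined pseudo-anomalies via a blurred-shape opacity
    mask and convex blending, a small residual convolutional network trained
    to distinguish original from augmented images, Gaussian kernel-density
    anomaly scoring over learned embeddings, best-F1 thresholding, and a full
    evaluation harness (ROC/AUC, accuracy, F1). A synthetic radiograph
    phantom generator with ground-truth lung masks makes the entire pipeline
    testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
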