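Package: senescreen
Title: Classification of Therapy-Induced Senescent Cells from Multimodal
    Nonlinear-Optical Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary classification of therapy-induced senescent versus
    proliferating cancer cells from co-registered three-channel label-free
    nonlinear-optical microscopy images (stimulated Raman scattering at the
    2850 cm-1 lipid mode, two-photon excited fluorescence of NADH/FAD, and
    optical transmission). Provides manifest-based image I/O with percentile
    outlier clipping, background suppression and 0-255 rescaling; a
    label-preserving augmentation stage (random rotation, translation and
    flips with zero fill); a compact convolutional neural-network engine
    with a from-scratch CNN, a transfer-learning classification head over a
    pluggable backbone registry, two-stage (frozen then fine-tuned) training
    with early stopping; a hybrid deep-feature + PCA + polynomial-SVM voting
    classifier; an unweighted probability-averaging ensemble; an evaluation
    harness (confusion metrics, ROC/AUC, multi-run summaries); Grad-CAM
    class-activation maps with a quantitative colocalization score; and a
    synthetic image generator emulating the senescent and control phenotypes
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
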