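Package: mpcadx
Title: Multiparametric Breast MRI Computer-Aided Diagnosis with Deep
    Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided diagnosis (CADx) pipeline for classifying breast
    lesions as benign or malignant from multiparametric MRI (dynamic
    contrast-enhanced plus T2-weighted sequences). Implements seeded fuzzy
    C-means lesion segmentation, automatic region-of-interest construction
    from second post-contrast subtraction maximum intensity projections and
    T2-weighted center slices, optional rigid mutual-information
    inter-sequence registration, multi-depth pooled feature extraction from a
    frozen 19-layer VGG-architecture convolutional backbone, class-weighted
    radial-basis support vector machine classification under nested
    patient-grouped cross-validation, three sequence-fusion schemes (image,
    feature, and classifier level), and the full evaluation layer: ROC/AUC,
    bootstrap confidence intervals, paired DeLong tests with Bonferroni-Holm
    correction, operating-point metrics, and AUC equivalence testing. A
    synthetic phantom module generates paired DCE/T2w cohorts with known
    ground truth so that every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
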