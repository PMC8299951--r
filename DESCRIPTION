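Package: habitex
Title: Intratumoral Habitat Texture Analysis for Dynamic Contrast-Enhanced Breast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for differentiating benign from malignant breast lesions on
    dynamic contrast-enhanced MRI via kinetic habitat partitioning and texture
    radiomics. Provides a synthetic DCE-MRI cohort generator with known ground
    truth, semi-automatic lesion segmentation (mu +/- 3 sigma normalization,
    8-bit quantization, spatial fuzzy C-means, morphological refinement),
    pixelwise time-to-peak mapping and early/moderate/late subregion
    partitioning, a 467-feature texture extractor (histogram, gray-level
    co-occurrence, gray-level run-length and discrete wavelet features),
    Pearson prefiltering with LASSO feature selection, decision-tree and
    support-vector classifiers under 10-fold cross-validation, and an
    evaluation toolkit (DeLong AUC confidence intervals and paired tests,
    Youden operating points, Lilliefors normality screening, univariate
    logistic AUC, two-way random-effects ICC).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    withr,
    glmnet,
    rpart,
    e1071,
    pROC,
    nortest,
    jsonlite,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
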