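Package: cardiopipe
Title: Multi-Modal Heart-Disease Diagnosis Pipeline with Hybrid Feature
    Selection, a Two-Pathway Deep Classifier, and Guideline-Constrained
    Nutrition Recommendation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale, fully testable implementation of a multi-phase
    clinical decision-support pipeline for cardiovascular diagnostics:
    per-modality preprocessing (wavelet denoising, min-max normalization,
    histogram equalization, bilinear resizing, mean imputation, z-score
    outlier handling, metadata cleaning), multi-feature extraction (HRV,
    QRS duration, periodogram band powers, shape descriptors, GLCM and
    LBP texture, statistical moments), hybrid ReliefF + Pearson feature
    selection, a configurable two-pathway CNN-Inception-LSTM classifier
    trained with a small in-package neural-network core, a nine-metric
    classification report, and a guideline-constrained Markov decision
    process for personalized nutrition recommendation optimized with
    proximal policy optimization (clipped surrogate, generalized
    advantage estimation, feasibility masking). Synthetic-data
    generators with known ground truth emulate every input modality so
    the whole pipeline runs and is tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
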