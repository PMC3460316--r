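Package: fcdiag
Title: Diagnostic Classification Pipelines for Multi-Site Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing personal-characteristic-based and resting-state
    fMRI-based diagnostic classification in multi-site pediatric ADHD cohorts.
    Implements spatial window averaging, brain masking, percent-signal-change
    normalization, temporal standardization, low-frequency Fourier and ALFF
    features, timecourse PCA features, group spatial ICA with GICA3
    back-reconstruction into per-participant functional-connectivity weighting
    maps, massively univariate t-maps with Monte-Carlo-calibrated cluster-size
    thresholding, statistical-mass-ordered cluster feature extraction (plain
    and robust leave-two-folds-out variants), counterbalanced 10-fold
    cross-validation with several classifier families, majority-class chance
    baselines, and a competition scoring rule. A synthetic-data module
    generates multi-site participant tables and 4D scans as linear mixtures of
    spatial sources with injected group effects, so the full analysis is
    testable end to end without access to restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    e1071,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
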