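Package: somatomap
Title: Somatotopic Digit-Map Remapping Analysis for Phase-Encoding and
    Block-Design fMRI with Tactile Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for short-term remapping of
    digit somatotopy in primary somatosensory cortex. Provides a synthetic
    cohort generator (2-D cortical sheet with Gaussian digit tuning, BOLD
    travelling-wave and block-design runs, temporal-order-judgment trials,
    and cued button-press confusion trials), travelling-wave phase-encoding
    analysis (lag-shifted gamma-HRF reference models, voxelwise
    cross-correlation, digit assignment, Fisher z maps, FDR thresholding),
    inter-digit overlap statistics (Dice coefficient, surface area, peak
    geodesic distance), representational similarity analysis (GLM,
    univariate noise normalisation, Euclidean RDMs, classical MDS, group
    Procrustes alignment), psychometric fitting of temporal order judgments
    (logistic fit, just-noticeable difference, goodness-of-fit exclusion),
    motor-confusion scoring, and the repeated-measures inferential suite
    (two-way within-subject ANOVA with partial eta squared,
    Greenhouse-Geisser correction, simple main effects, Sidak-corrected
    pairwise comparisons, Shapiro-Wilk screening, control-averaging
    sensitivity check).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    RNifti,
    knitr
Config/testthat/edition: 3
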