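Package: motormap
Title: Whole-Brain Motor-Mapping Group Analysis with TFCE Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing block-design motor-task fMRI at the group
    level: first-level general linear models with a canonical double-gamma
    haemodynamic response and temporal derivatives, fixed-effects averaging of
    effect estimates across runs, threshold-free cluster enhancement (TFCE)
    with max-statistic permutation family-wise error inference for one-sample
    and two-sample contrasts, activation-extent and spatial-similarity
    metrics, pairwise voxel-wise correlation variability statistics with
    permutation t-tests, and normalized structural-metric comparisons. A
    synthetic two-group cohort generator with known ground truth (activation
    footprints, amplitudes, between-subject jitter) makes every stage
    testable end-to-end without any imaging data download.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
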