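Package: taskconn
Title: Task-Evoked Brain Activation and Connectivity Analysis with
    Synthetic BOLD Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for event-related task fMRI studies of
    group differences and brain-behavior relationships: sparse-sampling
    paradigm generation, simulation of ROI-level and volumetric BOLD data
    with planted ground truth, volume despiking and motion-based quality
    control, single-subject general linear models with AR(1) prewhitening,
    Monte Carlo cluster-extent family-wise error correction, generalized
    psychophysiological interaction (gPPI) network connectivity, and
    multivariate prediction of group membership and behavioral scores with
    cross-validated support vector machines, penalized regression, and
    permutation-based inference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    e1071,
    glmnet,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
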