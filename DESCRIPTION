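Package: placebonet
Title: Voxel-Wise Degree Connectomes and Placebo-Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds whole-brain voxel-wise functional connectivity graphs at
    fixed link densities from resting-state fMRI time series, computes nodal
    degree-count maps across a density sweep, performs permutation-based
    two-group inference with threshold-free cluster enhancement (TFCE) and
    family-wise error correction, and carries a discovery-cohort linear fit of
    placebo analgesia on region-of-interest degree counts forward to a
    validation cohort, including the additive placebo/drug decomposition of
    drug-arm responses. Ships a synthetic-cohort generator with a latent-factor
    signal model so the whole pipeline is testable end to end without imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
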