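Package: atnseq
Title: Model Evidence for Monotone Gray-Matter Decline Across ATN Biomarker Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deciding which ordered sequence of ATN
    (amyloid/tau/neurodegeneration) biomarker conversions best explains
    monotone gray-matter volume decline in a cross-sectional cohort.
    Provides ATN classification from CSF and volumetric biomarker panels
    (fixed, Youden, or Gaussian-mixture cutoffs, with covariate adjustment
    of hippocampal volume), enumeration of candidate progression sequences
    (all 24 permutations of the AD-continuum groups and the 6 three-step
    conversion paths), per-outcome constrained least-squares fits under
    monotone-decline constraints, BIC model-evidence comparison across
    sequences, voxel-wise winner maps with FDR-corrected trend statistics,
    ROI and Braak-stage composite summaries, and a synthetic-data generator
    that emulates the assumed cohort and image structure with stored ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
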