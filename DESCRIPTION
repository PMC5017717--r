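Package: liverreg
Title: Two-Stage Deformable Registration of Liver CT for Image-Guided
    Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deformable registration of a diagnostic contrast-enhanced
    liver CT onto intra-operative CT images acquired during percutaneous
    tumor ablation.  Implements masked multiresolution B-spline free-form
    registration driven by mutual information with stochastic sampling, a
    user-guided refinement step that penalizes non-rigid deformation
    inside seed-point regions (local rigidity regularization), and a
    second stage that carries the tumor annotation into limited
    field-of-view needle-check scans via an intermediate rigid
    registration.  Ships quantitative evaluation metrics (Dice overlap,
    mean surface distance, landmark correspondence distance), a synthetic
    deformable CT phantom generator with ground-truth transforms for
    validation, MetaImage/NIfTI input and output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
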