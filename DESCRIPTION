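Package: radrobust
Title: Radiomic Feature Robustness Databanks via Image Perturbation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds test-retest style robustness databanks for CT radiomic
    features without rescanning patients. Volumes with tumour masks are
    perturbed by sub-voxel translation, in-plane rotation, scaled additive
    noise and randomized contours; shape, first-order and texture features
    (GLCM, GLRLM, GLSZM, GLDM, NGTDM) are extracted from unfiltered,
    Laplacian-of-Gaussian filtered and wavelet-filtered images after
    isotropic resampling, HU resegmentation and fixed-bin-count
    discretization; per-feature repeatability is scored with the one-way
    random-effects intraclass correlation coefficient and classified, with
    resampled confidence intervals and sample-size dependence curves.
    Repeatability-preselected features feed a proportional-hazards modelling
    workflow (univariate screening, bootstrap LASSO frequency selection,
    concordance evaluation) whose transportability is summarized by a
    generalizability index. A synthetic CT phantom generator with linked
    survival outcomes makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    survival,
    glmnet,
    jsonlite,
    tools,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
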