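Package: svrlsm
Title: Multivariate Support Vector Regression Lesion-Symptom Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate lesion-symptom mapping of post-stroke depression
    using epsilon support vector regression with a radial basis function
    kernel (SVR-LSM). Provides MADRS symptom-domain scoring (conceptual and
    data-driven via principal components with oblique rotation), lesion
    matrix assembly from binary NIfTI masks with a minimum-overlap filter,
    lesion-volume and confound correction, permutation-based voxel-wise
    inference with Gaussian smoothing of thresholded maps, Dice overlap
    comparison of significance maps, atlas-based cluster labelling, and a
    synthetic lesion-cohort simulator with planted ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    kernlab,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
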