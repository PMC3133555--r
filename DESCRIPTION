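Package: splsda
Title: Sparse Partial Least Squares Discriminant Analysis for
    High-Dimensional Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multiclass feature selection and classification for
    high-dimensional expression and genotype matrices via sparse partial
    least squares discriminant analysis (sPLS-DA). Each latent dimension
    is fit by an L1 soft-thresholded rank-one decomposition of the
    cross-product between the predictor block and a dummy-coded class
    response, with sparsity parameterized as the number of features kept
    per dimension (keepX). Includes repeated stratified cross-validation
    for tuning the number of dimensions and selection sizes, bootstrap
    stability analysis of the selected features, minor-allele-frequency
    filtering for 0/1/2 genotype matrices, synthetic multiclass data
    generators with planted informative features, and projection-based
    visualization outputs (sample score plots, loading-weight plots,
    correlation circles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
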