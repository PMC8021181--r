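Package: myelinmetric
Title: Unsupervised Metric Learning of Myelin and Cellularity from
    T2-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Texture-based tissue segmentation and microstructure feature
    estimation for small-animal spinal cord MRI. Implements a Gaussian
    Markov random field (GMRF) segmentation with annealed Gibbs sampling,
    pseudo-likelihood parameter estimation and Gibbs-sampler texture
    simulation; unsupervised metric learning that maps precision-scaled
    Mahalanobis distances to a histology (myelin, cellularity) space by
    multilateration; supervised segmentation-regression and additive-model
    comparators with leave-one-out cross-validation; evaluation utilities
    (confusion matrices, Pearson and binomial confidence intervals,
    ROC/AUC with DeLong comparison, cohort median maps); and a seeded
    synthetic spinal-cord phantom generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mclust,
    pROC,
    png,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
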