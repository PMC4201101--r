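Package: mmfs
Title: Multimodal Feature Selection and Classification for Disease Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative classification of multimodal subject-level features
    (MRI and PET region-of-interest measures, CSF biomarkers, and SNP
    genotypes) along the HC/MCI/AD diagnostic spectrum.  Implements three
    sparse and structured feature-selection learners -- simplex-constrained
    multiple kernel learning, high-order graph-matching regularized
    regression, and sparse multimodal learning with joint group and row
    l2,1 penalties -- together with unsupervised SNP screening scores
    (Laplacian score and a local/global variance ratio), train-fitted
    normalization schemes, a weighted-feature linear-SVM classification
    protocol with stratified 10-fold cross-validation and grid search, and
    a synthetic multimodal data generator for fully reproducible
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    glmnet,
    yaml,
    optparse
Config/testthat/edition: 3
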