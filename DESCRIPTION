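Package: sixmApred
Title: Prediction of DNA N6-Methyladenine Sites from 41-bp Windows
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies 41-bp plant DNA windows as N6-methyladenine (6mA)
    or non-6mA sites. Each window is encoded three ways per nucleotide
    (one-hot, nucleotide chemical properties, electron-ion interaction
    potential) and the concatenated 328-dimensional feature vector is
    reduced by an elastic-net regression fitted on training data only;
    the retained features feed a small one-dimensional convolutional
    network trained by stochastic gradient descent with early stopping.
    Includes stratified five-fold cross-validation, confusion-matrix
    metrics (accuracy, sensitivity, specificity, Matthews correlation),
    ROC and precision-recall curves with the prevalence baseline for
    imbalanced evaluation, class-ratio subsampling for cross-species
    benchmarks, and a motif-planting simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, MethylSeq, Classification, FeatureExtraction,
    Sequencing
RoxygenNote: 7.3.3
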