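Package: methylGA
Title: Nested Genetic-Algorithm Feature Selection and Neural
    Classification for DNA Methylation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised CpG feature selection for Illumina-style DNA
    methylation beta-value matrices using a nested two-layer genetic
    algorithm: an outer binary feature-selection GA scored by an inner
    grouping GA that partitions samples and evaluates the
    Calinski-Harabasz cluster-validity index on the masked feature
    space. Includes beta-value preprocessing (missing-value filtering
    and per-sample linear imputation), a synthetic-cohort generator
    with known informative loci, multilayer-perceptron classifiers for
    binary malignancy and pan-cancer typing trained with Adam, and an
    evaluation suite (confusion matrices, Matthews correlation
    coefficient, one-vs-rest ROC with micro/macro AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    Rcpp,
    parallel
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: DNAMethylation, FeatureExtraction, Classification, Clustering
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
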