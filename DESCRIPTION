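Package: herdclust
Title: Herd Clustering on Mixed Social-Ecological Data and Herd-Cluster
    Contemporary Groups in Dairy Genetic Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Clusters dairy farms described by mixed-type survey variables
    (quantitative, nominal, ordinal, symmetric and asymmetric binary) with
    a Gower dissimilarity, four competing algorithms (Ward agglomerative
    clustering, partitioning around medoids, fuzzy clustering, and
    clustering of variables followed by hierarchical clustering of the
    resulting synthetic variables), and average-silhouette-width model
    selection. The selected herd clusters replace single herds in
    contemporary-group definitions of a pedigree-based repeatability
    test-day animal model: Henderson mixed-model equations, EM-REML
    variance components, BLUP breeding values and prediction-error-variance
    reliabilities, with side-by-side comparison of herd-test-day,
    herd-cluster-test-day, herd-test-month and herd-cluster-test-month
    contemporary groups. Includes seed-deterministic generators for
    surveys, pedigrees, test-day and fertility records with planted
    structure and known variance components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    Matrix,
    stats,
    utils,
    lme4,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
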