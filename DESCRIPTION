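Package: sparseStages
Title: Robust Sparse k-Means Clustering of Lifespan Molecular Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for partitioning small-sample, high-dimensional molecular
    datasets (protein or gene expression across the lifespan) into age-related
    clusters using sparse k-means with lasso-type feature weights and its
    robust, outlier-trimmed extension. Includes data-driven selection of the
    number of clusters from the weighted within-cluster sum of squares with
    Savitzky-Golay curvature detection, permutation-based tuning of the L1
    weight bound, multi-restart consensus analysis with co-assignment counts
    and Jaccard cluster overlap, an age-randomization null for cluster-age
    progression, over-representation calls against a simulated normal null,
    PCA cos2 quality-of-representation with Bland-Altman agreement against
    clustering weights, construction and validation of composite phenotype
    features (protein sums and contrast indices), LOESS lifespan trajectories,
    age-binned cross-omics pair correlations, and a synthetic lifespan-data
    generator with planted stage structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
biocViews: Clustering, GeneExpression, Proteomics, DimensionReduction
RoxygenNote: 7.3.3
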