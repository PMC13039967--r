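Package: metabotyper
Title: Metabotype Discovery from Clinical and Untargeted Metabolomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-step framework for discovering clinical metabotypes in
    cohort studies of metabolic liver disease. Step one clusters a panel of
    ten routine clinical variables with k-means, selects the number of
    clusters from a panel of internal validity indices, and tests cluster
    stability against a column-permutation null. Step two processes
    untargeted LC-MS feature tables (replicate summarization, CV filtering,
    empirical-Bayes batch adjustment, cross-study feature matching, quantile
    normalization, multivariate outlier screening), performs per-feature
    ANOVA with FDR control and Tukey post-hoc tests, runs permutation-based
    m/z pathway enrichment with adduct mass matching, builds per-metabotype
    clinical-metabolite association networks via two-block PLS in canonical
    mode, and selects features by differential eigenvector centrality. A
    synthetic-cohort generator with planted cluster structure, pathway
    effects, and batch artifacts makes every stage testable without access
    to controlled clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    limma,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    sva,
    withr
Config/testthat/edition: 3
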