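Package: amonet
Title: Diversity and Co-Occurrence Network Analysis for Amplicon OTU Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end community analysis for amplicon OTU count tables,
    built around ammonia-oxidizer (amoA) community studies but applicable to
    any OTU-by-sample table. Provides rarefaction to even depth, Shannon and
    Chao1 alpha diversity, Bray-Curtis dissimilarity with principal
    coordinates analysis and ANOSIM permutation testing, and
    Spearman-thresholded co-occurrence network inference with topological
    metrics, Louvain module detection, and Guimera-Amaral Zi-Pi node-role
    classification. A negative-binomial Gaussian-copula simulator generates
    OTU tables with known group structure and planted correlation modules so
    every stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
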