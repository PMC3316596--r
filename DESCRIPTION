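Package: bagc3net
Title: Bagged C3NET Inference of Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers undirected gene regulatory networks from gene expression
    data by bootstrap aggregation (bagging) of the C3NET algorithm. An
    ensemble of networks is inferred from non-parametric bootstrap resamples
    of the expression matrix, aggregated into edge frequencies, and each gene
    pair is tested against a binomial null whose chance-edge probability is
    estimated from randomized data; Bonferroni correction over all gene pairs
    yields the final network. Includes eight interchangeable mutual
    information estimators (empirical, Miller-Madow, shrinkage,
    Schuermann-Grassberger, B-spline, and correlation-based), three
    randomization schemes for the mutual information null, a Hill-kinetics
    expression simulator with Erdos-Renyi and subnetwork ground truths,
    precision/recall/F-score evaluation, and gene-pair enrichment analysis
    (GPEA) against gene-set collections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
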