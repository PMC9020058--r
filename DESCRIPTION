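Package: deregnet
Title: Maximally Deregulated Subnetworks in Directed Biomolecular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Finds maximally deregulated, root-connected subgraphs of a
    directed biomolecular network by maximizing (or minimizing) the average
    node deregulation score via fractional integer programming, solved with a
    Dinkelbach-type iterative scheme over an exact branch-and-bound core.
    Includes the underlying Bernoulli deregulation model with per-subgraph
    maximum-likelihood rate estimation, multi-omics node-score constructors
    (trinary and personalized expression scores, promoter-methylation gene
    scores, methylation-transcription consistency scores), a planted-subgraph
    simulation benchmark with standard recovery metrics and hypergeometric
    gene-set-enrichment comparison, and survival stratification by subgraph
    membership (network-defined cancer genes, Kaplan-Meier and log-rank).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
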