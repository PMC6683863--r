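Package: phosphonet
Title: Time-Resolved Signalling Network Inference from Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for receptor-triggered phosphoproteomic
    signalling analysis: spike-in (global internal standard) normalization of
    light/heavy phosphopeptide intensities, per-time-point differential
    phosphosite testing with Benjamini-Hochberg correction and fold-change
    target calling, kinase-activity inference by permutation-normalized
    substrate-set enrichment and by fuzzy c-means time-course clustering with
    Fisher enrichment, assembly and pruning of a prior-knowledge
    kinase-substrate / protein-protein network, and exact Integer Linear
    Programming selection of a Boolean signalling subnetwork connecting the
    receptor to its regulated sites, evolved across time points with
    bootstrap consensus edge weights and entry times. A synthetic-data module
    generates ground-truth networks and noisy time-course datasets so the
    whole pipeline can be benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
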