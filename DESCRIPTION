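Package: kmerpan
Title: Reference-Free Pangenome Analysis via Canonical k-mer Indexing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds a reference-free, alignment-free pangenome representation
    from canonical k-mer presence/absence across many genome assemblies or
    read sets. Provides a compact on-disk k-mer index, pairwise similarity
    statistics (shared k-mers, Jaccard, ANI, MerQury-style QV), hierarchical
    clustering with heatmaps, genome-anchored k-mer conservation tracks for
    locus-level core/variable analysis, a two-panel introgression block
    caller, and a seeded synthetic-pangenome generator for testing and
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    stringi,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
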