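Package: loopnest
Title: Hierarchical Loop Decomposition of Weighted Planar Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps weighted planar ("loopy") networks, such as digitized leaf
    venation or cortical vasculature, to binary nesting trees by iteratively
    removing the weakest edge and merging the two adjacent loops. Provides tree
    metrics that quantify the hierarchical architecture of the original graph
    (van Pelt partition and subtree asymmetry, cumulative and adjusted loop
    size distributions, Horton-Strahler orders, stream counts and the
    bifurcation ratio), seeded generators for triangular-lattice model
    networks (gradient, random links, nested and partially shuffled nested,
    random lines, peaks), nesting-tree based segmentation into sectors,
    partition-asymmetry based data cleaning, readers and writers for edge-list
    TSV, GraphML, annotated Newick and JSON, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
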