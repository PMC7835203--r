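Package: rnni
Title: Ranked Nearest Neighbour Interchange Distances Between Ranked
    Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for ranked phylogenetic trees, i.e. rooted binary
    leaf-labelled trees whose internal nodes carry a strict temporal
    ordering (ranks).  Implements the ranked nearest neighbour
    interchange (RNNI) rearrangement graph with a weight parameter rho
    on rank swaps, and the FindPath algorithm, which constructs provably
    shortest paths between two ranked trees in the unit-weight graph in
    quadratic time.  Includes exhaustive enumeration and uniform random
    sampling of ranked trees, an exact brute-force shortest-path oracle
    for small leaf counts, conversion between cluster-representation
    strings and ultrametric Newick, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
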