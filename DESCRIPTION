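Package: nestcomp
Title: Ancestral Compatibility and Supertrees for Semi-Labeled Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests whether a collection of rooted semi-labeled trees
    (phylogenies and taxonomies, where internal nodes may carry
    higher-order taxon labels) is ancestrally compatible, and builds a
    supertree that preserves every ancestor/descendant and
    incomparability relationship of the inputs when it is.  The engine
    works on the display graph of the profile, identifies semi-universal
    labels from per-component bookkeeping, and tracks component splits
    with a decremental dynamic-connectivity structure so that the running
    time is near-linear in the total size of the input trees and
    independent of node degrees.  Includes Newick input/output for trees
    with labels on arbitrary nodes, deterministic generators of
    compatible and incompatible test profiles, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ape
Config/testthat/edition: 3
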