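Package: rxnmine
Title: Reaction Network Construction and Exhaustive Synthetic Route Mining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds bipartite reaction-molecule networks (networks of organic
    chemistry) from reaction SMILES strings, with validation, canonicalization,
    role reassignment and identifier-based deduplication. Provides an in-memory
    graph store with idempotent merge semantics, network statistics,
    predicate-based subgraph selection and synthetic-tree extraction, and an
    exhaustive enumerator of all valid synthetic routes to a target molecule
    under user-defined bounds (maximum linear sequence length, stop-marked
    starting materials). Ships a 27-node abstract benchmark graph, minimal
    challenge scenarios, a seeded random AND/OR network generator, a
    brute-force reference enumerator used as a correctness oracle, and
    exporters to node/edge tables, canonical graph JSON and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ChemmineOB,
    jsonlite,
    igraph,
    yaml,
    utils,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
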