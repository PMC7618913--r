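Package: circuitgraph
Title: Knowledge-Graph Analysis and Integration of Genetic Circuit Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts genetic designs (SBOL3, SBOL2, GenBank) into a canonical
    typed knowledge graph and back, derives analytical projections of the graph
    (parts hierarchy, regulatory interaction networks, derived protein
    networks), combines multiple designs with set-algebraic load predicates,
    validates and expands graph-level edits into the design format, and merges
    multi-source part repositories with synonym detection and identity-weighted
    derivative edges. Includes deterministic fixture generators for synthetic
    designs and part corpora, graph exports (GraphML, node-link JSON, edge-list
    CSV), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    xml2,
    jsonlite,
    yaml,
    Biostrings,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
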