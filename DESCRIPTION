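Package: mepnkit
Title: Machine-Operable mEPN Pathway Diagrams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for working with pathway diagrams drawn in the modified
    Edinburgh Pathway Notation (mEPN). Reads and writes the yEd dialect of
    GraphML used for such diagrams (preserving PubMed evidence, Entrez links
    and layout), validates notation rules such as the one-occurrence-per-
    compartment uniqueness rule, computes network statistics (node-class
    census, connectivity, diameter), merges independently curated pathway
    modules, exports interaction-evidence tables, compiles diagrams into
    signalling Petri nets for stochastic token-flow simulation, and overlays
    expression-derived class-sets onto pathway nodes, including a built-in
    co-expression pipeline (fold-change/p-value filter, Pearson correlation
    graph, Markov clustering). Deterministic synthetic-pathway and
    synthetic-expression generators make every step testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
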