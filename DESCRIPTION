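Package: nestnet
Title: Hierarchical Nested Networks, Dendrogram Superimposition and
    Force-Directed Layout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-layer hierarchical (compound) graphs: an
    undirected weighted network at the leaf level together with a
    containment forest of nested containers above it. Superimposes
    hierarchical clusterings onto networks as nested modules, aggregates
    inter-module connectivity into edge densities, and computes nested
    force-directed layouts in which members are held inside their
    container by restoring forces. Includes seeded generators for modular
    graphs, preferential-attachment scale-free interactomes and synthetic
    time-course differential-expression sets, readers and writers for
    compound GraphML, JSON and edge-list formats, an SVG renderer, and
    end-to-end co-expression and time-course nesting workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
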