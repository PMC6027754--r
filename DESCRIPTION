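Package: provdag
Title: Aggregation and Exploration of Workflow Data Provenance Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for summarizing and exploring data provenance graphs
    produced by file-based bioinformatics workflow systems. Provenance is
    modeled as a directed acyclic graph of tool, file, and raw-data nodes
    organized into a hierarchy of workflow instances, analysis input groups,
    and analyses. The package aggregates this hierarchy bottom-up and further
    compresses repeated analyses into motif-based layers keyed by workflow
    template and upstream provenance context, computes a per-layer change
    metric that flags re-runs, and drives per-node aggregation levels with a
    modular degree-of-interest function. A column-based layered layout with
    barycentric crossing reduction, facet and time filtering, path tracing,
    and deterministic SVG, DOT, and GraphML export turn a mixed-level view
    into static figures and structural exports. A synthetic generator emits a
    simulated multi-factor ChIP-seq study (and randomized provenance graphs)
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
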