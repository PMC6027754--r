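# provdag — aggregation and exploration of workflow data provenance graphs

Workflow platforms that process biomedical studies file by file (Galaxy-style
systems and the data-management layers around them) record a complete data
provenance graph: every tool execution, every derived file, every raw input.
For a study with dozens of samples pushed through several multi-step
pipelines this DAG quickly reaches hundreds of nodes — too large to read as a
flat node-link diagram, yet indispensable for answering *which workflows ran,
in what order, what changed between repeated runs, and which raw data a
result depends on*.

provdag is an R toolkit that makes such graphs explorable:

* **Hierarchical aggregation** along the inherent provenance hierarchy:
  workflow instances (AL0) → analysis input groups (AL1) → analyses (AL2).
* **Motif-based layers (AL3)**: analyses sharing a workflow template *and*
  the same upstream provenance context merge into a single layer node, so
  the compressed graph still shows how workflows were chained.
* **A per-layer change metric**: each layer member is compared to the
  layer's earliest run on input/output/group counts
  (`delta = |Δin| + |Δout| + |Δgroups|`, layer delta = max over members,
  normalized by the global maximum); a positive delta flags re-runs and
  modified executions with an asterisk.
* **A modular degree-of-interest (DoI) function**
  `doi(a) = Σ wᵢ·vᵢ` with `Σ wᵢ = 1`, over five components — filter,
  highlight, selection (binary user actions) and execution-time recency,
  layer delta (continuous attributes) — that selects each analysis's
  displayed aggregation level and extracts high-interest analyses from
  otherwise collapsed layers.
* **Layered grid layout** (longest-path columns, barycentric crossing
  reduction, spreadsheet-style coordinates), **facet/time filtering** with
  blend or hide semantics, **path tracing** up/down the DAG, and
  byte-stable **SVG / DOT / GraphML export**.
* **A synthetic study generator** reproducing a simulated ChIP-seq design
  (2 modifications × 2 tissues × 3 treatments × 2 replicates = 24 raw files,
  five chained workflows, multiple sessions, one unconsumed re-run), plus a
  randomized generator for property testing — everything is testable without
  external data.

## Worked example

```r
library(provdag)

sc <- generate_chipseq()        # the simulated ChIP-seq study
sc$graph
#> <provenance_graph> 510 nodes (218 tools, 268 files, 24 raw), 486 edges
#>   5 templates, 194 groups, 9 analyses

layers <- compute_layer_deltas(assign_layers(sc$graph), sc$graph)
layers
#> <prov_layers> 5 layer(s)
#>   layer-1: template wt-qc, context [ROOT], 1 member(s)
#>   layer-2: template wt-mapping, context [ROOT], 1 member(s)
#>   layer-3: template wt-macs2, context [layer-2], 3 member(s) *
#>   layer-4: template wt-spp, context [layer-2], 2 member(s)
#>   layer-5: template wt-pileup, context [layer-3, layer-4], 2 member(s)
```

The 9 analyses collapse into 5 layers — one per workflow role, because the
two peak callers both consume Mapping output and Pileup consumes both peak
callers. The asterisk on `layer-3` is the change metric at work: the MACS2
layer contains the late re-run on a single pair of kidney files (2 inputs /
4 outputs / 2 groups against the earliest member's 12 / 24 / 12, raw delta
40, normalized 1), while all other layers are unchanged.

```r
st <- view_state(sc$graph)                     # default DoI: equal weights
r  <- resolve_display(st, override_level = "AL3")
r$display
#> <display_graph> 29 nodes (AL0 24, AL1 0, AL2 0, AL3 5), 52 edges

writeLines(to_svg(r$display, r$layout), "study-al3.svg")
writeLines(export_graph(r$display, "GraphML"), "study-al3.graphml")

# which results came from one kidney raw file?
down <- trace(st, "raw-H3K4me3-kidney-Mock-r1", "DOWN")
length(down)
#> [1] 21
```

The fully aggregated view is 29 display nodes (5 layers + 24 raw files);
the SVG shades nodes white→black by execution age, draws layers with a
time gradient and dashed outline, and marks exactly one layer with the
change asterisk. The downstream trace shows the kidney file flowing through
QC, Mapping, *both* peak callers, and Pileup — 21 base nodes in total.
Interest-driven mixed views come from the same state: concentrate DoI
weight on `HIGHLIGHT` after `expand_path()` and the traced pipeline expands
to full detail while everything else stays collapsed.

A command-line wrapper covers the same pipeline
(`generate` / `stats` / `view` / `trace`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/provdag.R", package = "provdag"))')
Rscript "$CLI" generate --out-json study.json --out-tsv study.tsv
Rscript "$CLI" view --in study.json --svg study.svg --all-level AL3
```

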