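---
title: "Aggregating and exploring workflow provenance graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregating and exploring workflow provenance graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provdag)
```

## The problem

File-based workflow platforms (Galaxy-style systems and the data-management
layers built on them) record, for every analysis they run, which tools
consumed which files and what came out. Over the lifetime of a study this
data provenance forms a directed acyclic graph that is both broad — every
raw sequencing file is pushed through the same workflows — and deep, with
a dozen or more steps between a raw file and a final result. A flat
node-link drawing of such a graph is unreadable at a few hundred nodes,
yet analysts need it to answer concrete questions: which workflows ran,
in what order, what changed between repeated runs, and which raw data a
given result depends on.

provdag addresses this by aggregating the graph along two axes and letting
a scalar interest function decide, per analysis, how much detail to show.

## The data model

The provenance hierarchy has four levels:

* **AL0 — workflow instances**: the base DAG of tool, derived-file, and raw
  input nodes. Edges alternate strictly (`FILE`/`RAW -> TOOL`,
  `TOOL -> FILE`): a file is never produced from a file without a tool in
  between, and tools never feed tools directly.
* **AL1 — analysis input groups**: one independent execution of a workflow
  template on one input set. Groups partition all non-raw nodes.
* **AL2 — analyses**: one workflow-template execution over a set of input
  files at one timestamp; an analysis owns one group per input set, and
  every group belongs to exactly one analysis.
* **AL3 — layers**: motif-based aggregates of analyses, described next.

Raw input files sit outside the hierarchy (they belong to the dataset, not
to any execution) and are always drawn individually. An analysis's
*outputs* are its member files that either have no consumer inside the
analysis or have at least one consumer outside it; purely internal
intermediates are not outputs. The model fixes timestamps as integer epoch
seconds in UTC so that ordering is total and timezone-free.

## Motif-based layers

Aggregating analyses purely by workflow template would merge runs that play
entirely different roles — a mapping step applied to raw data and the same
mapping template applied to someone else's processed output. A layer
therefore merges analyses that share *both* their template *and* their
upstream provenance context. Analyses are processed in a deterministic
topological order (ties broken by execution time, then id); the context of
an analysis is the sorted set of layer ids already assigned to its direct
predecessor analyses, with a `ROOT` sentinel for source analyses. An
analysis joins the layer keyed by `(context, template)`, creating it if
absent.

Two properties follow. First, membership partitions the analyses. Second,
an analysis can never share a layer with one of its own predecessors (its
context would contain that layer), so edges between layers always point
from earlier-created to later-created layers and the layer-contracted graph
remains acyclic. The direct-predecessor context is the weakest constraint
that still separates same-template analyses with different provenance; a
`strict = TRUE` mode uses the full upstream layer-id chain instead, which
splits layers whose members agree on parents but differ further upstream.
The default is the weaker mode because it reproduces the intended study
structure (one layer per workflow role) without fragmenting long pipelines.

### The change metric

Within a layer, every member is compared to the member with the earliest
execution time (ties by id): the member delta is the sum of absolute
differences in input count, output count, and group count. The layer's raw
delta is the **maximum** member delta — a deliberate choice over the mean,
so that a single diverging re-run flags the whole layer no matter how many
unchanged runs surround it. Raw deltas are normalized across layers by the
global maximum (all zeros when nothing changed), which maps the
most-changed layer to 1 and keeps the value inside `[0, 1]` for use as a
DoI component. A layer is *changed* (asterisk in renderings) iff its raw
delta is positive.

## The degree-of-interest function

Each analysis gets a DoI value

$$\mathrm{doi}(a) = \sum_{i=1}^{n} w_i \, v_i, \qquad \sum_i w_i = 1,$$

over five components: three binary user actions — `FILTER` (the analysis
passes the active facet/time filter), `HIGHLIGHT` (it lies on a traced
path), `SELECTED` (it was explicitly chosen) — and two continuous
attributes — `TIME`, execution time min-max normalized over all analyses,
and `DELTA`, the normalized change metric of the containing layer. `TIME`
rewards recency (the most recent run scores 1): sessions of interest are
typically the latest ones, and the degenerate single-time case maps to 0.

Weights default to 0.2 each with all components enabled. Setting one weight
rescales the others by `(1 - new)/(1 - old)` so the sum stays 1 (split
equally when the old weight was 1); disabling a component redistributes its
weight proportionally, and re-enabling one grants it `1/n`. All operations
keep the sum within `1e-9` of 1, so the DoI itself is always in `[0, 1]`.

The DoI value selects the aggregation level through thresholds
`t1 < t2 < t3` (defaults 0.25 / 0.5 / 0.75): `[0, t1)` collapses to the
layer (AL3), `[t1, t2)` shows the analysis node (AL2), `[t2, t3)` its
groups (AL1), and `[t3, 1]` full detail (AL0). Intervals are
lower-inclusive so a value sitting exactly on a threshold resolves
deterministically to the more detailed side. **Extraction** handles the
boundary case where one analysis in a layer is interesting but the layer as
a whole is not: an analysis whose DoI reaches `t_x` (default 0.25) while
its layer still has collapsed members is drawn as its own analysis node
attached to the layer by a dashed link, instead of silently disappearing
into it. With the default thresholds `t_x` coincides with `t1`, so
extraction is exactly the set of AL2-resolved analyses whose layers remain
on screen.

User-action flags are set per analysis; a flag placed on any base node
propagates to its owning analysis (and tracing a path flags every analysis
that owns a traced node), since the DoI drives levels per analysis.

## Filtering, tracing, resolution

A filter has a facet part (attribute name to allowed values) and a time
range. An analysis passes when its time is in range and, for each facet
entry, at least one input file of one of its groups carries an allowed
value — sample metadata (tissue, treatment, ...) lives on files, and the
generator propagates factor attributes from raw files to derived ones, so
downstream analyses remain facetable. `BLEND` mode only dims non-passing
analyses (node and edge counts are unchanged); `HIDE` removes them and, by
default, raw files left without any visible consumer. Hiding removes whole
analyses, never individual files, which keeps the hierarchy partition
intact.

Tracing computes the full predecessor (`UP`) or successor (`DOWN`) closure
of a base node, inclusive, together with every edge on such paths
(reachability is delegated to igraph; the test suite checks it against an
independent exhaustive closure). `expand_path()` turns a trace into
`HIGHLIGHT` flags; with weight concentrated on `HIGHLIGHT` this expands the
traced pipeline to full detail while everything else stays collapsed.

`resolve_display()` puts it together: component values, DoI, levels (or a
global override level, the equivalent of a "show everything at AL2"
toolbar button), extraction, hidden-set removal, display induction, and
layout. It is a pure function of the state: resolving twice yields
identical objects.

## Layout

Columns come from longest-path layering: the column of a node is the length
of the longest path reaching it. This guarantees every edge points strictly
left-to-right, which breadth-first depth does not; the cost is long
straight edges across intermediate columns, which are accepted rather than
broken at dummy nodes — a property of the grid design, where the widest
node in a column sets the column width anyway (spreadsheet model). Rows
start in (execution time, id) order and are refined by alternating 2-layer
barycenter sweeps (default 4), counting crossings exactly between adjacent
columns after each sweep and keeping the best ordering seen — the result
never has more crossings than the initial order, and on small bipartite
instances it stays within 1.5x of the exhaustive one-sided optimum in the
suite's seeded cases. Coordinates place rows on a common grid followed by a
single mean-neighbor centering pass that moves a node only when its column
stays collision-free; this replaces a full multi-pass alignment scheme at a
fraction of the complexity and aligns simple chains exactly.

## Rendering

AL0 glyphs are diamonds (tools), squares (raw data), and circles (files);
aggregates are rectangles with a level badge (`G`/`A`/`L`), their direct
child count, and — for layers — the total workflow-instance count. Fill
encodes age on a white (earliest) to black (most recent) linear ramp over
the graph-wide time range; layers get a two-stop gradient from their
earliest to their latest member's shade. A two-stop gradient deliberately
summarizes rather than reproduces the within-layer time distribution.
Changed layers carry an asterisk and a dashed outline. Label display uses a
deterministic rule (AL0: the node label or a chosen attribute; aggregates:
workflow name plus counts) instead of pixel-space elision, which would be
renderer-specific. Elements are emitted in sorted-id order with fixed
number formatting, so the same state always produces byte-identical SVG,
DOT, and GraphML — renderings are reproducible artifacts, not screenshots.

## The synthetic study

`generate_chipseq()` emulates the provenance of a simulated ChIP-seq study:
2 histone modifications (H3K27ac, H3K4me3) x 2 tissues (kidney, liver) x 3
treatments (Alpha, Beta, Mock) x 2 replicates = 24 raw files over 12 factor
combinations, processed by five workflow templates — QC (one tool, one
report), Mapping (two chained tools with one intermediate file), the MACS2
and SPP peak callers (one tool, two peak files each), and Pileup (one tool,
one file). Session 1 runs QC and Mapping over everything plus the liver
branch of peak calling and pileup; session 2 (two weeks later) the kidney
branch; a third event re-runs MACS2 on one pair of kidney files and leaves
the outputs unconsumed. The re-run shares template and context with the
session runs, so it lands in the existing MACS2 layer and makes it the only
changed layer (delta `(12-2) + (24-4) + (12-2) = 40`, normalized 1) — the
canonical "what changed here?" exploration target.

Peak callers are modeled with a single data input (no control track) and
internal template shapes are defaults, not measurements; both are
configurable. One analysis is created per workflow and session, with one
input group per file. The generator emulates provenance *structure* only:
node labels use genomics file names, but no sequence data, tool parameters,
or runtimes exist, and real studies vary session composition, arities, and
user behavior far more. Passing tests therefore demonstrate correctness of
the graph machinery on realistic topology, not robustness to the full
messiness of production metadata. `generate_random()` complements it with
seeded random — but always invariant-satisfying — graphs for property
tests.

## Numerical and degenerate-input choices

* Weight-sum tolerance `1e-9`; weights renormalize after every operation
  rather than accumulating drift.
* All ties (topological order, layer member order, row order, serialization
  order) break by `(execution_time, id)` with C-locale byte order for ids,
  so every result is reproducible across platforms and locales. Equal-time
  members of a layer are legal; the earliest-member reference is then the
  lexicographically first.
* Degenerate ranges: a single execution time maps to `TIME = 0` and shade
  white; an all-identical layer has delta 0; an empty graph serializes,
  validates, renders, and lays out without special-casing by callers.
* Problem sizes in the checks were chosen to keep the full suite fast while
  still exercising the combinatorics: 1000 random graphs of up to 30
  analyses for the layer properties, exhaustive permutation oracles up to 7
  nodes per side, exhaustive reachability up to 60 nodes.

## Known limitations

* Layer identity (`layer-1`, `layer-2`, ...) is stable for a fixed graph
  but not across graph edits; diffing two provenance snapshots is out of
  scope.
* The barycenter heuristic has no optimality guarantee beyond the measured
  guard; pathological bipartite instances can stay above the optimum.
* Layout is recomputed from scratch per view; there is no incremental
  relayout preserving positions across interactions, and no animation —
  the package produces static, reproducible artifacts.
* Faceting matches group *input* attributes only; attributes attached to
  tools are ignored.
* The provenance document is this package's own versioned format. Adapters
  for platform APIs or ISA-Tab metadata are intentionally not included; the
  TSV metadata export is a simplified stand-in.
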