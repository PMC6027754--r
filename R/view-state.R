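# Session state: filters, tracing, path-driven expansion, and resolution of
# the final mixed-level display from DoI values.

#' Facet and time filter specification
#'
#' An analysis passes when its execution time lies in `time_range` and, for
#' every facet entry, at least one input file of one of its groups carries an
#' allowed attribute value. `BLEND` keeps non-passing analyses visible at
#' reduced opacity; `HIDE` removes them (and, by default, raw files left
#' without visible consumers).
#'
#' @param facet named list, attribute name -> character vector of allowed
#'   values; empty list passes everything.
#' @param time_range numeric `c(lo, hi)` epoch seconds, `lo <= hi`;
#'   `c(-Inf, Inf)` passes everything.
#' @param mode `"BLEND"` or `"HIDE"`.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(facet = list(), time_range = c(-Inf, Inf),
                        mode = c("BLEND", "HIDE")) {
  mode <- match.arg(mode)
  if (length(time_range) != 2L || anyNA(time_range) || time_range[1] > time_range[2]) {
    stopf("time_range must be c(lo, hi) with lo <= hi")
  }
  if (length(facet) > 0L && is.null(names(facet))) {
    stopf("facet must be a named list of allowed values")
  }
  structure(list(facet = facet, time_range = as.numeric(time_range), mode = mode),
            class = "filter_spec")
}

#' Create a view state
#'
#' Bundles a provenance graph with its layers and everything that defines the
#' current view: DoI weights and thresholds, user-action flags, the active
#' filter, traced nodes and highlighted edges, and the hidden/dimmed analysis
#' sets.
#'
#' @param graph a valid `provenance_graph`.
#' @param layers precomputed layers; defaults to
#'   `compute_layer_deltas(assign_layers(graph), graph)`.
#' @param weights a [doi_weights()].
#' @param config a [doi_config()].
#' @return object of class `view_state`.
#' @export
view_state <- function(graph, layers = NULL, weights = doi_weights(),
                       config = doi_config()) {
  if (is.null(layers)) layers <- compute_layer_deltas(assign_layers(graph), graph)
  structure(list(
    graph = graph, layers = layers, weights = weights, config = config,
    flags = list(filter = character(), highlight = character(),
                 selected = character()),
    filter = NULL, hidden = character(), dimmed = character(),
    traced = character(), highlighted_edges = empty_df(c("source", "target"))
  ), class = "view_state")
}

#' Apply a facet/time filter
#'
#' Evaluates the filter over all analyses, sets the `FILTER` DoI flag on
#' passing ones, and dims (`BLEND`) or hides (`HIDE`) the rest.
#'
#' @param state a `view_state`.
#' @param spec a [filter_spec()].
#' @return the updated `view_state`.
#' @export
apply_filter <- function(state, spec) {
  if (!inherits(spec, "filter_spec")) stopf("spec must be a filter_spec")
  graph <- state$graph
  an <- graph$analyses
  passes <- vapply(an$id, function(a) analysis_passes_filter(graph, a, spec),
                   logical(1))
  passing <- an$id[passes]
  failing <- an$id[!passes]
  state$filter <- spec
  state$flags$filter <- passing
  if (spec$mode == "BLEND") {
    state$dimmed <- failing
    state$hidden <- character()
  } else {
    state$hidden <- failing
    state$dimmed <- character()
  }
  state
}

analysis_passes_filter <- function(graph, analysis_id, spec) {
  i <- match(analysis_id, graph$analyses$id)
  t <- graph$analyses$execution_time[i]
  if (t < spec$time_range[1] || t > spec$time_range[2]) return(FALSE)
  if (length(spec$facet) == 0L) return(TRUE)
  gids <- graph$analyses$group_ids[[i]]
  inputs <- unique(unlist(graph$groups$input_file_ids[match(gids, graph$groups$id)],
                          use.names = FALSE))
  in_attrs <- graph$nodes$attrs[match(inputs, graph$nodes$id)]
  for (nm in names(spec$facet)) {
    allowed <- spec$facet[[nm]]
    hit <- any(vapply(in_attrs, function(a) {
      nm %in% names(a) && a[[nm]] %in% allowed
    }, logical(1)))
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Trace predecessors or successors of a node
#'
#' `UP` returns every base node with a directed path to the given node
#' (inclusive); `DOWN` every node reachable from it (inclusive). The edges
#' lying on any such path are attached as attribute `"edges"`.
#'
#' @param state a `view_state` (or a `provenance_graph`).
#' @param node_id a base node id.
#' @param direction `"UP"` or `"DOWN"`.
#' @return character vector of base node ids, with attribute `edges`
#'   (data.frame `source`, `target`).
#' @export
trace <- function(state, node_id, direction = c("UP", "DOWN")) {
  direction <- match.arg(direction)
  graph <- if (inherits(state, "view_state")) state$graph else state
  if (!(node_id %in% graph$nodes$id)) stopf("unknown node id '%s'", node_id)
  ig <- igraph::graph_from_data_frame(
    graph$edges, directed = TRUE,
    vertices = data.frame(name = graph$nodes$id, stringsAsFactors = FALSE)
  )
  mode <- if (direction == "UP") "in" else "out"
  reach <- igraph::subcomponent(ig, node_id, mode = mode)
  ids <- sort_c(names(reach))
  e <- graph$edges
  on_path <- e$source %in% ids & e$target %in% ids
  attr(ids, "edges") <- e[on_path, , drop = FALSE]
  ids
}

#' Highlight and expand a traced path
#'
#' Traces from `node_id`, stores the traced node and edge sets in the state,
#' and sets the `HIGHLIGHT` DoI flag on every analysis owning a traced node —
#' with a positive `HIGHLIGHT` weight this raises their DoI and hence their
#' level of detail, while all other analyses keep their flags.
#'
#' @param state a `view_state`.
#' @param node_id a base node id.
#' @param direction `"UP"` or `"DOWN"`.
#' @return the updated `view_state`.
#' @export
expand_path <- function(state, node_id, direction = c("UP", "DOWN")) {
  direction <- match.arg(direction)
  traced <- trace(state, node_id, direction)
  owner <- analysis_of_node_map(state$graph)
  owners <- sort_c(unique(unname(owner[intersect(traced, names(owner))])))
  state$traced <- as.character(traced)
  state$highlighted_edges <- attr(traced, "edges")
  rownames(state$highlighted_edges) <- NULL
  state$flags$highlight <- sort_c(unique(c(state$flags$highlight, owners)))
  state
}

#' Resolve the current display graph and layout
#'
#' Computes per-analysis DoI values from the state's flags and weights, maps
#' them to aggregation levels (or applies `override_level` everywhere),
#' determines extractions, removes hidden analyses, induces the display
#' graph, transfers dim/highlight marks, and lays it out. Calling it twice on
#' the same state yields identical results.
#'
#' @param state a `view_state`.
#' @param config a [doi_config()]; defaults to the state's.
#' @param override_level force a single aggregation level for all analyses
#'   (the toolbar's "set all nodes to level X"); `NULL` to use the DoI.
#' @param sizes a [size_model()].
#' @return list with `display` (a `display_graph`, annotated), `layout` (a
#'   `layout_result`), and `doi` (named numeric vector per analysis).
#' @export
resolve_display <- function(state, config = NULL, override_level = NULL,
                            sizes = size_model()) {
  config <- config %||% state$config
  graph <- state$graph
  v <- compute_component_values(graph, state$layers, state$flags)
  doi <- vapply(rownames(v) %||% character(),
                function(a) compute_doi(v[a, ], state$weights), numeric(1))
  levels <- if (!is.null(override_level)) {
    if (!(override_level %in% AGGREGATION_LEVELS)) {
      stopf("override_level must be one of %s", paste(AGGREGATION_LEVELS, collapse = ", "))
    }
    stats::setNames(rep(override_level, length(doi)), names(doi))
  } else {
    stats::setNames(level_for_doi(unname(doi), config), names(doi))
  }

  layer_of <- attr(state$layers, "layer_of")
  # extraction: analyses expanded to AL2 whose layer still shows merged members
  extracted <- character(0)
  if (is.null(override_level)) {
    al3_layers <- unique(layer_of[names(levels)[levels == "AL3" &
                                                  !(names(levels) %in% state$hidden)]])
    cand <- names(doi)[doi >= config$t_x & levels == "AL2" &
                         !(names(doi) %in% state$hidden)]
    extracted <- cand[layer_of[cand] %in% al3_layers]
    levels[extracted] <- "AL3"  # extracted nodes are induced beside their layer
  }

  display <- induce_display(graph, state$layers, levels,
                            extracted = extracted, hidden = state$hidden,
                            drop_orphan_raw = !is.null(state$filter) &&
                              state$filter$mode == "HIDE")

  # transfer dim marks: an aggregate is dimmed when all its analyses are
  if (length(state$dimmed) > 0L) {
    owner <- analysis_of_node_map(graph)
    display$nodes$dimmed <- vapply(seq_len(nrow(display$nodes)), function(i) {
      nd <- display$nodes[i, ]
      owners <- switch(nd$level,
        AL0 = if (nd$kind == "RAW") character() else unname(owner[[nd$entity_id]]),
        AL1 = graph$groups$analysis_id[match(nd$entity_id, graph$groups$id)],
        AL2 = nd$entity_id,
        AL3 = state$layers$members[[match(nd$entity_id, state$layers$id)]]
      )
      length(owners) > 0L && all(owners %in% state$dimmed)
    }, logical(1))
  }

  # transfer highlighted edges onto display edges
  if (nrow(state$highlighted_edges) > 0L) {
    m <- display$mapping
    he <- state$highlighted_edges
    keep <- he$source %in% names(m) & he$target %in% names(m)
    hfrom <- unname(m[he$source[keep]])
    hto <- unname(m[he$target[keep]])
    keys <- unique(paste(hfrom, hto)[hfrom != hto])
    attr(display, "highlighted_display_edges") <- keys
    display$nodes$highlighted <- display$nodes$id %in% unique(c(hfrom, hto))
  }

  layout <- layout_display(display, sizes = sizes)
  list(display = display, layout = layout, doi = doi)
}

#' Timeline histogram of analysis activity
#'
#' Bins analyses on execution time; the height of a bin is the total number
#' of analysis input groups executed in it (the quantity a timeline view puts
#' on the y axis).
#'
#' @param graph a valid `provenance_graph`.
#' @param bin_width bin width in seconds (default one day).
#' @return data.frame with `bin_start`, `bin_end`, `n_analyses`, `n_groups`.
#' @export
timeline_bins <- function(graph, bin_width = 86400) {
  an <- graph$analyses
  if (nrow(an) == 0L) {
    return(data.frame(bin_start = numeric(), bin_end = numeric(),
                      n_analyses = integer(), n_groups = integer()))
  }
  b0 <- floor(min(an$execution_time) / bin_width) * bin_width
  idx <- floor((an$execution_time - b0) / bin_width)
  ng <- lengths(an$group_ids)
  agg <- stats::aggregate(cbind(n_analyses = rep(1L, nrow(an)), n_groups = ng),
                          by = list(bin = idx), FUN = sum)
  data.frame(bin_start = b0 + agg$bin * bin_width,
             bin_end = b0 + (agg$bin + 1) * bin_width,
             n_analyses = as.integer(agg$n_analyses),
             n_groups = as.integer(agg$n_groups))
}

#' Save or restore the interactive part of a view state
#'
#' Serializes weights, thresholds, flags, filter, hidden/dimmed sets, and the
#' traced selection as JSON (the graph itself is saved separately with
#' [save_provenance()]); `load_view_state()` re-attaches them to a graph.
#'
#' @param state a `view_state`.
#' @param path optional file path.
#' @return JSON text (invisibly when `path` is given).
#' @export
save_view_state <- function(state, path = NULL) {
  ub <- jsonlite::unbox
  doc <- list(
    weights = as.list(state$weights$w),
    enabled = as.list(state$weights$enabled),
    thresholds = lapply(state$config, ub),
    flags = lapply(state$flags, as.list),
    filter = if (is.null(state$filter)) NULL else list(
      facet = lapply(state$filter$facet, as.list),
      time_range = state$filter$time_range,
      mode = ub(state$filter$mode)
    ),
    hidden = as.list(state$hidden),
    dimmed = as.list(state$dimmed),
    traced = as.list(state$traced),
    highlighted_edges = if (nrow(state$highlighted_edges) == 0L) list() else
      lapply(seq_len(nrow(state$highlighted_edges)), function(i) {
        list(source = ub(state$highlighted_edges$source[i]),
             target = ub(state$highlighted_edges$target[i]))
      })
  )
  txt <- paste0(jsonlite::toJSON(doc, pretty = 2, digits = NA, null = "null",
                                 auto_unbox = FALSE), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' @rdname save_view_state
#' @param graph the `provenance_graph` the state belongs to.
#' @param json JSON text or file path produced by `save_view_state()`.
#' @export
load_view_state <- function(graph, json) {
  txt <- if (grepl("^\\s*\\{", json)) json else
    paste(readLines(json, warn = FALSE), collapse = "\n")
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  chr <- function(x) as.character(unlist(x) %||% character())
  w <- vapply(doc$weights, as.numeric, numeric(1))
  state <- view_state(
    graph,
    weights = doi_weights(w[chr(doc$enabled)], enabled = chr(doc$enabled)),
    config = doi_config(doc$thresholds$t1, doc$thresholds$t2,
                        doc$thresholds$t3, doc$thresholds$t_x)
  )
  state$flags <- lapply(doc$flags, chr)
  if (!is.null(doc$filter)) {
    spec <- filter_spec(
      facet = lapply(doc$filter$facet, chr),
      time_range = vapply(doc$filter$time_range, as.numeric, numeric(1)),
      mode = doc$filter$mode
    )
    state <- apply_filter(state, spec)
    state$flags <- lapply(doc$flags, chr)  # restore exactly as saved
  }
  state$hidden <- chr(doc$hidden)
  state$dimmed <- chr(doc$dimmed)
  state$traced <- chr(doc$traced)
  he <- doc$highlighted_edges
  state$highlighted_edges <- if (length(he) == 0L) empty_df(c("source", "target")) else
    data.frame(source = vapply(he, function(x) x$source, character(1)),
               target = vapply(he, function(x) x$target, character(1)),
               stringsAsFactors = FALSE)
  state
}
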