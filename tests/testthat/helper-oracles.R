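# Independent oracles and small graph builders used across the suite.
# Oracles are deliberately naive (exhaustive enumeration, fixpoint closures)
# and share no code with the implementation they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- reachability by fixpoint closure over the raw edge list ------------------
oracle_reach <- function(edges, start, direction) {
  reach <- start
  repeat {
    nxt <- if (direction == "DOWN") {
      edges$target[edges$source %in% reach]
    } else {
      edges$source[edges$target %in% reach]
    }
    new <- setdiff(nxt, reach)
    if (length(new) == 0L) break
    reach <- c(reach, new)
  }
  sort(reach, method = "radix")
}

# -- quotient contraction of an edge list under a node -> class mapping -------
oracle_quotient <- function(edges, mapping) {
  if (nrow(edges) == 0L) return(character())
  keep <- edges$source %in% names(mapping) & edges$target %in% names(mapping)
  qs <- unname(mapping[edges$source[keep]])
  qt <- unname(mapping[edges$target[keep]])
  sort(unique(paste(qs, qt)[qs != qt]), method = "radix")
}

# -- longest path from any source, by exhaustive path enumeration ------------
oracle_longest_path <- function(edges, node) {
  preds <- edges$source[edges$target == node]
  if (length(preds) == 0L) return(0L)
  1L + max(vapply(preds, function(p) oracle_longest_path(edges, p), integer(1)))
}

# -- crossing count of a 2-column instance via pairwise inversions -----------
# edges: data.frame(from, to); pos_left/pos_right: named rank vectors
oracle_crossings <- function(edges, pos_left, pos_right) {
  n <- nrow(edges)
  if (n < 2L) return(0L)
  total <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dl <- pos_left[[edges$from[i]]] - pos_left[[edges$from[j]]]
      dr <- pos_right[[edges$to[i]]] - pos_right[[edges$to[j]]]
      if (dl * dr < 0) total <- total + 1L
    }
  }
  total
}

# minimum crossings over all permutations of the right column (left fixed)
oracle_min_crossings_right <- function(edges, left_order, right_ids) {
  pos_left <- stats::setNames(seq_along(left_order), left_order)
  perms <- all_perms(right_ids)
  min(vapply(perms, function(p) {
    oracle_crossings(edges, pos_left, stats::setNames(seq_along(p), p))
  }, integer(1)))
}

all_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# -- builders -----------------------------------------------------------------

# minimal display-graph stub: nodes at AL2 with given ids/times, explicit edges
mk_display <- function(ids, edges, times = NULL) {
  times <- times %||% seq_along(ids)
  nodes <- data.frame(
    id = ids, level = "AL2", kind = NA_character_, entity_id = ids,
    label = ids, child_count = 1L, total_base_count = 1L,
    sort_time = times, time_min = times, time_max = times,
    delta_raw = 0L, delta_norm = 0, box = NA_character_,
    extracted = FALSE, dimmed = FALSE, highlighted = FALSE,
    stringsAsFactors = FALSE
  )
  e <- if (is.null(edges) || nrow(edges) == 0L) {
    data.frame(from = character(), to = character(), kind = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = edges$from, to = edges$to, kind = "flow",
               stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = e,
                 mapping = stats::setNames(ids, ids),
                 time_range = range(times)),
            class = "display_graph")
}

# the classic single-analysis example: one 1-in/1-out template applied to
# n input files -> n groups, each raw_i -> tool_i -> out_i
single_template_graph <- function(n_files = 10L, time = 1000) {
  raw <- sprintf("raw%02d", seq_len(n_files))
  tool <- sprintf("tool%02d", seq_len(n_files))
  outf <- sprintf("out%02d", seq_len(n_files))
  gid <- sprintf("g%02d", seq_len(n_files))
  nodes <- data.frame(
    id = c(raw, tool, outf),
    kind = c(rep("RAW", n_files), rep("TOOL", n_files), rep("FILE", n_files)),
    label = c(raw, tool, outf),
    group_id = c(rep(NA_character_, n_files), gid, gid),
    stringsAsFactors = FALSE
  )
  nodes$attrs <- rep(list(character()), nrow(nodes))
  edges <- data.frame(source = c(raw, tool), target = c(tool, outf),
                      stringsAsFactors = FALSE)
  templates <- data.frame(id = "wt1", name = "onestep",
                          inputs_per_group = 1L, outputs_per_group = 1L,
                          stringsAsFactors = FALSE)
  templates$tool_names <- list("onestep_tool")
  groups <- data.frame(id = gid, analysis_id = "a1", stringsAsFactors = FALSE)
  groups$member_node_ids <- mapply(function(t, o) c(t, o), tool, outf,
                                   SIMPLIFY = FALSE, USE.NAMES = FALSE)
  groups$input_file_ids <- as.list(raw)
  analyses <- data.frame(id = "a1", template_id = "wt1", execution_time = time,
                         user = NA_character_, stringsAsFactors = FALSE)
  analyses$group_ids <- list(gid)
  provenance_graph(nodes, edges, templates, groups, analyses)
}

# chain of k analyses, each consuming the previous one's output
# (same template throughout), starting from one raw file
chained_graph <- function(k = 2L, template_per_analysis = NULL) {
  tpl <- template_per_analysis %||% rep("wt1", k)
  utpl <- unique(tpl)
  nodes <- data.frame(id = "raw1", kind = "RAW", label = "raw1",
                      group_id = NA_character_, stringsAsFactors = FALSE)
  nodes$attrs <- list(character())
  edges <- NULL; groups <- NULL; analyses <- NULL
  prev <- "raw1"
  for (i in seq_len(k)) {
    aid <- sprintf("a%d", i); gid <- sprintf("a%d-g1", i)
    tid <- sprintf("a%d-t1", i); fid <- sprintf("a%d-f1", i)
    nd <- data.frame(id = c(tid, fid), kind = c("TOOL", "FILE"),
                     label = c(tid, fid), group_id = gid,
                     stringsAsFactors = FALSE)
    nd$attrs <- rep(list(character()), 2)
    nodes <- rbind(nodes, nd)
    edges <- rbind(edges, data.frame(source = c(prev, tid), target = c(tid, fid),
                                     stringsAsFactors = FALSE))
    gr <- data.frame(id = gid, analysis_id = aid, stringsAsFactors = FALSE)
    gr$member_node_ids <- list(c(tid, fid))
    gr$input_file_ids <- list(prev)
    groups <- rbind(groups, gr)
    an <- data.frame(id = aid, template_id = tpl[i], execution_time = 1000 + i,
                     user = NA_character_, stringsAsFactors = FALSE)
    an$group_ids <- list(gid)
    analyses <- rbind(analyses, an)
    prev <- fid
  }
  templates <- data.frame(id = utpl, name = utpl, inputs_per_group = 1L,
                          outputs_per_group = 1L, stringsAsFactors = FALSE)
  templates$tool_names <- rep(list("step"), length(utpl))
  provenance_graph(nodes, edges, templates, groups, analyses)
}

# mapping base node -> display node implied by an all-AL3 view, for quotient
# oracles: raw files stay individual, grouped nodes go to their layer node
al3_mapping <- function(graph, layers) {
  layer_of <- attr(layers, "layer_of")
  owner <- provdag:::analysis_of_node_map(graph)
  m <- character()
  for (i in seq_len(nrow(graph$nodes))) {
    id <- graph$nodes$id[i]
    m[[id]] <- if (graph$nodes$kind[i] == "RAW") paste0("n:", id) else
      paste0("l:", layer_of[[owner[[id]]]])
  }
  m
}

default_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_chipseq()
    cache
  }
})
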