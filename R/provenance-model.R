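#' Construct a provenance graph
#'
#' A provenance graph is the full, unaggregated (AL0) record of a set of
#' workflow executions: a directed acyclic graph whose nodes are tools,
#' derived files, and raw input files, together with the hierarchy that
#' organizes them — analysis input groups (one independent workflow instance
#' each, AL1) and analyses (one workflow-template execution over a set of
#' input files at a timestamp, AL2).
#'
#' All tables are canonicalized on construction: rows are sorted by id in
#' C-locale byte order, node attribute maps are sorted by name, and row names
#' are dropped. Two graphs with the same content therefore compare equal with
#' [identical()] regardless of input row order.
#'
#' @param nodes data.frame with columns `id`, `kind` (`"TOOL"`, `"FILE"`, or
#'   `"RAW"`), `label`, `group_id` (`NA` for raw inputs), and a list column
#'   `attrs` of named character vectors (sample metadata such as tissue or
#'   file name).
#' @param edges data.frame with columns `source`, `target`. Edges must
#'   alternate between data and computation: `FILE`/`RAW -> TOOL` or
#'   `TOOL -> FILE`.
#' @param templates data.frame with columns `id`, `name`, `inputs_per_group`,
#'   `outputs_per_group` and a list column `tool_names`.
#' @param groups data.frame with columns `id`, `analysis_id` and list columns
#'   `member_node_ids` (tools + derived files of one workflow instance) and
#'   `input_file_ids` (consumed files, always outside the group).
#' @param analyses data.frame with columns `id`, `template_id`,
#'   `execution_time` (integer epoch seconds, UTC), `user` (optional,
#'   `NA` allowed) and a list column `group_ids`.
#' @param validate if `TRUE` (default), run [validate_graph()] and fail on any
#'   violation.
#' @return An object of class `provenance_graph`.
#' @seealso [load_provenance()], [validate_graph()], [generate_chipseq()]
#' @export
provenance_graph <- function(nodes = NULL, edges = NULL, templates = NULL,
                             groups = NULL, analyses = NULL, validate = TRUE) {
  g <- structure(
    list(
      nodes     = canon_nodes(nodes),
      edges     = canon_edges(edges),
      templates = canon_templates(templates),
      groups    = canon_groups(groups),
      analyses  = canon_analyses(analyses)
    ),
    class = "provenance_graph"
  )
  if (validate) {
    v <- validate_graph(g)
    if (nrow(v) > 0L) {
      stopf(
        "invalid provenance graph (%d violation%s):\n%s",
        nrow(v), if (nrow(v) == 1L) "" else "s",
        paste(sprintf("  [%s] %s: %s", v$code, v$entity_id, v$message),
              collapse = "\n")
      )
    }
  }
  g
}

empty_df <- function(cols, list_cols = character()) {
  out <- as.data.frame(
    stats::setNames(rep(list(character()), length(cols)), cols),
    stringsAsFactors = FALSE
  )
  for (lc in list_cols) out[[lc]] <- list()
  out
}

canon_nodes <- function(nodes) {
  if (is.null(nodes) || nrow(nodes) == 0L) {
    return(empty_df(c("id", "kind", "label", "group_id"), "attrs"))
  }
  if (is.null(nodes$group_id)) nodes$group_id <- NA_character_
  if (is.null(nodes$attrs)) nodes$attrs <- rep(list(character()), nrow(nodes))
  nodes <- nodes[order_c(nodes$id), c("id", "kind", "label", "group_id", "attrs")]
  nodes$group_id <- as.character(nodes$group_id)
  nodes$attrs <- unname(lapply(nodes$attrs, function(a) {
    if (length(a) == 0L) return(stats::setNames(character(), character()))
    a <- vapply(a, as.character, character(1))
    a[order_c(names(a))]
  }))
  rownames(nodes) <- NULL
  nodes
}

canon_edges <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) return(empty_df(c("source", "target")))
  edges <- edges[order_c(edges$source, edges$target), c("source", "target")]
  rownames(edges) <- NULL
  edges
}

canon_templates <- function(templates) {
  if (is.null(templates) || nrow(templates) == 0L) {
    out <- empty_df(c("id", "name"), "tool_names")
    out$inputs_per_group <- integer()
    out$outputs_per_group <- integer()
    return(out[c("id", "name", "tool_names", "inputs_per_group", "outputs_per_group")])
  }
  templates <- templates[order_c(templates$id),
                         c("id", "name", "tool_names", "inputs_per_group",
                           "outputs_per_group")]
  templates$tool_names <- unname(lapply(templates$tool_names, as.character))
  templates$inputs_per_group <- as.integer(templates$inputs_per_group)
  templates$outputs_per_group <- as.integer(templates$outputs_per_group)
  rownames(templates) <- NULL
  templates
}

canon_groups <- function(groups) {
  if (is.null(groups) || nrow(groups) == 0L) {
    return(empty_df(c("id", "analysis_id"), c("member_node_ids", "input_file_ids")))
  }
  groups <- groups[order_c(groups$id),
                   c("id", "analysis_id", "member_node_ids", "input_file_ids")]
  groups$member_node_ids <- unname(lapply(groups$member_node_ids,
                                          function(x) sort_c(as.character(x))))
  # input file order is meaningful (template input slots) and preserved
  groups$input_file_ids <- unname(lapply(groups$input_file_ids, as.character))
  rownames(groups) <- NULL
  groups
}

canon_analyses <- function(analyses) {
  if (is.null(analyses) || nrow(analyses) == 0L) {
    out <- empty_df(c("id", "template_id"), "group_ids")
    out$execution_time <- numeric()
    out$user <- character()
    return(out[c("id", "template_id", "execution_time", "group_ids", "user")])
  }
  if (is.null(analyses$user)) analyses$user <- NA_character_
  analyses <- analyses[order_c(analyses$id),
                       c("id", "template_id", "execution_time", "group_ids", "user")]
  analyses$execution_time <- as.numeric(analyses$execution_time)
  analyses$group_ids <- unname(lapply(analyses$group_ids, as.character))
  analyses$user <- as.character(analyses$user)
  rownames(analyses) <- NULL
  analyses
}

#' @export
print.provenance_graph <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind, levels = NODE_KINDS))
  cat(sprintf(
    paste0("<provenance_graph> %d nodes (%d tools, %d files, %d raw), ",
           "%d edges\n  %d templates, %d groups, %d analyses\n"),
    nrow(x$nodes), kinds[["TOOL"]], kinds[["FILE"]], kinds[["RAW"]],
    nrow(x$edges), nrow(x$templates), nrow(x$groups), nrow(x$analyses)
  ))
  invisible(x)
}

# ---- internal lookup helpers -------------------------------------------------

node_kind_map <- function(graph) stats::setNames(graph$nodes$kind, graph$nodes$id)

# analysis owning each grouped (non-RAW) node
analysis_of_node_map <- function(graph) {
  if (nrow(graph$groups) == 0L) return(stats::setNames(character(), character()))
  n <- lengths(graph$groups$member_node_ids)
  stats::setNames(rep(graph$groups$analysis_id, n),
                  unlist(graph$groups$member_node_ids, use.names = FALSE))
}

group_of_node_map <- function(graph) {
  if (nrow(graph$groups) == 0L) return(stats::setNames(character(), character()))
  n <- lengths(graph$groups$member_node_ids)
  stats::setNames(rep(graph$groups$id, n),
                  unlist(graph$groups$member_node_ids, use.names = FALSE))
}

out_adjacency <- function(graph) {
  adj <- stats::setNames(vector("list", nrow(graph$nodes)), graph$nodes$id)
  if (nrow(graph$edges) > 0L) {
    sp <- split(graph$edges$target, graph$edges$source)
    adj[names(sp)] <- sp
  }
  adj
}

in_adjacency <- function(graph) {
  adj <- stats::setNames(vector("list", nrow(graph$nodes)), graph$nodes$id)
  if (nrow(graph$edges) > 0L) {
    sp <- split(graph$edges$source, graph$edges$target)
    adj[names(sp)] <- sp
  }
  adj
}

# ---- validation --------------------------------------------------------------

#' Validate a provenance graph
#'
#' Checks every structural invariant of the provenance model and returns the
#' violations as data rather than raising errors, so callers can report all
#' problems at once.
#'
#' Checked invariants: unique ids; known node kinds; raw inputs carry no
#' group; tools and derived files belong to exactly one existing group, and
#' the group lists them as members; edge endpoints exist, no self-loops, and
#' edges alternate `FILE`/`RAW -> TOOL` or `TOOL -> FILE`; the node graph is
#' acyclic; group member sets are disjoint and group input files are not
#' members; analyses reference one existing template and a non-empty set of
#' groups, each group belongs to exactly one analysis, and the group's back
#' reference agrees.
#'
#' @param graph a `provenance_graph` (possibly built with `validate = FALSE`).
#' @return data.frame with columns `code`, `message`, `entity_id`; zero rows
#'   iff the graph is valid.
#' @export
validate_graph <- function(graph) {
  v <- list()
  add <- function(code, message, entity_id) {
    v[[length(v) + 1L]] <<- data.frame(code = code, message = message,
                                       entity_id = entity_id,
                                       stringsAsFactors = FALSE)
  }

  nodes <- graph$nodes; edges <- graph$edges
  groups <- graph$groups; analyses <- graph$analyses; templates <- graph$templates

  for (tab in list(list("node", nodes$id), list("group", groups$id),
                   list("analysis", analyses$id), list("template", templates$id))) {
    dup <- unique(tab[[2]][duplicated(tab[[2]])])
    for (d in dup) add("duplicate-id", sprintf("duplicate %s id", tab[[1]]), d)
  }

  bad_kind <- nodes$id[!(nodes$kind %in% NODE_KINDS)]
  for (id in bad_kind) add("bad-kind", "unknown node kind", id)

  group_ids <- groups$id
  raw_grouped <- nodes$id[nodes$kind == "RAW" & !is.na(nodes$group_id)]
  for (id in raw_grouped) add("raw-grouped", "RAW node must not have a group", id)
  non_raw <- nodes[nodes$kind %in% c("TOOL", "FILE"), , drop = FALSE]
  for (i in seq_len(nrow(non_raw))) {
    gid <- non_raw$group_id[i]
    if (is.na(gid)) {
      add("missing-group", "TOOL/FILE node must belong to a group", non_raw$id[i])
    } else if (!(gid %in% group_ids)) {
      add("dangling-group", sprintf("node references unknown group '%s'", gid),
          non_raw$id[i])
    }
  }

  node_ids <- nodes$id
  kind <- node_kind_map(graph)
  if (nrow(edges) > 0L) {
    for (i in seq_len(nrow(edges))) {
      s <- edges$source[i]; t <- edges$target[i]
      eid <- paste0(s, "->", t)
      if (!(s %in% node_ids) || !(t %in% node_ids)) {
        add("dangling-edge", "edge endpoint does not exist", eid)
        next
      }
      if (s == t) { add("self-loop", "self-loop not allowed", eid); next }
      ks <- kind[[s]]; kt <- kind[[t]]
      ok <- (ks %in% c("FILE", "RAW") && kt == "TOOL") ||
        (ks == "TOOL" && kt == "FILE")
      if (!ok) {
        add("non-alternating",
            sprintf("edge must be FILE/RAW->TOOL or TOOL->FILE, got %s('%s')->%s('%s')",
                    ks, s, kt, t), eid)
      }
    }
  }

  cyc <- find_cycle(node_ids, edges)
  if (!is.null(cyc)) {
    add("cycle", paste0("cycle: ", paste(cyc, collapse = " -> ")), cyc[[1]])
  }

  # group membership: disjoint, existing, consistent with node$group_id
  member_all <- unlist(groups$member_node_ids, use.names = FALSE)
  dup_members <- unique(member_all[duplicated(member_all)])
  for (id in dup_members) add("membership", "node is member of two groups", id)
  gmap <- group_of_node_map(graph)
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    missing <- setdiff(g$member_node_ids[[1]], node_ids)
    for (id in missing) add("dangling-member",
                            sprintf("group '%s' lists unknown member", g$id), id)
    inside <- intersect(g$input_file_ids[[1]], g$member_node_ids[[1]])
    for (id in inside) add("input-is-member",
                           sprintf("input file of group '%s' is also a member", g$id), id)
    missing_in <- setdiff(g$input_file_ids[[1]], node_ids)
    for (id in missing_in) add("dangling-input",
                               sprintf("group '%s' lists unknown input file", g$id), id)
    if (!(g$analysis_id %in% analyses$id)) {
      add("dangling-analysis-ref",
          sprintf("group references unknown analysis '%s'", g$analysis_id), g$id)
    }
  }
  for (i in seq_len(nrow(non_raw))) {
    id <- non_raw$id[i]; gid <- non_raw$group_id[i]
    if (!is.na(gid) && gid %in% group_ids &&
        !(id %in% groups$member_node_ids[[match(gid, groups$id)]])) {
      add("membership",
          sprintf("node's group '%s' does not list it as a member", gid), id)
    }
  }

  # analyses
  owner <- stats::setNames(rep(NA_character_, length(group_ids)), group_ids)
  for (i in seq_len(nrow(analyses))) {
    a <- analyses[i, ]
    if (!(a$template_id %in% templates$id)) {
      add("dangling-template",
          sprintf("analysis references unknown template '%s'", a$template_id), a$id)
    }
    gids <- a$group_ids[[1]]
    if (length(gids) == 0L) add("empty-analysis", "analysis has no groups", a$id)
    for (gid in gids) {
      if (!(gid %in% group_ids)) {
        add("dangling-group-ref",
            sprintf("analysis lists unknown group '%s'", gid), a$id)
      } else {
        if (!is.na(owner[[gid]])) {
          add("shared-group",
              sprintf("group listed by analyses '%s' and '%s'", owner[[gid]], a$id),
              gid)
        }
        owner[[gid]] <- a$id
        back <- groups$analysis_id[match(gid, groups$id)]
        if (!is.na(back) && back != a$id) {
          add("group-analysis-mismatch",
              sprintf("group '%s' claims analysis '%s' but is listed by '%s'",
                      gid, back, a$id), gid)
        }
      }
    }
  }
  orphan <- group_ids[is.na(owner[group_ids])]
  for (gid in orphan) add("orphan-group", "group not listed by any analysis", gid)

  if (length(v) == 0L) {
    return(data.frame(code = character(), message = character(),
                      entity_id = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

# Iterative DFS cycle finder; returns one cycle as a vector of node ids, or NULL.
find_cycle <- function(node_ids, edges) {
  if (nrow(edges) == 0L || length(node_ids) == 0L) return(NULL)
  adj <- stats::setNames(vector("list", length(node_ids)), node_ids)
  sp <- split(edges$target, edges$source)
  adj[names(sp)] <- sp
  color <- stats::setNames(rep(0L, length(node_ids)), node_ids)  # 0 new, 1 open, 2 done
  for (root in node_ids) {
    if (color[[root]] != 0L) next
    stack <- list(list(node = root, next_i = 1L))
    color[[root]] <- 1L
    path <- root
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      nbrs <- adj[[top$node]]
      if (is.null(nbrs) || top$next_i > length(nbrs)) {
        color[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
        path <- path[-length(path)]
        next
      }
      stack[[length(stack)]]$next_i <- top$next_i + 1L
      nb <- nbrs[[top$next_i]]
      if (!(nb %in% node_ids)) next
      if (color[[nb]] == 1L) {
        i <- match(nb, path)
        return(c(path[i:length(path)], nb))
      }
      if (color[[nb]] == 0L) {
        color[[nb]] <- 1L
        stack[[length(stack) + 1L]] <- list(node = nb, next_i = 1L)
        path <- c(path, nb)
      }
    }
  }
  NULL
}

# ---- analysis-level DAG ------------------------------------------------------

#' Analysis-level dependency DAG
#'
#' Lifts the file-level provenance DAG to the analysis level: analysis `A`
#' precedes analysis `B` iff a file produced inside `A` is an input file of
#' one of `B`'s groups. The returned topological order is deterministic: ties
#' are broken by `(execution_time, id)` ascending.
#'
#' @param graph a valid `provenance_graph`.
#' @return list with `edges` (data.frame `from`, `to`, deduplicated) and
#'   `order` (character vector of analysis ids).
#' @export
analysis_dag <- function(graph) {
  an <- graph$analyses
  if (nrow(an) == 0L) {
    return(list(edges = empty_df(c("from", "to")), order = character()))
  }
  producer <- analysis_of_node_map(graph)
  grp <- graph$groups
  grp_analysis <- stats::setNames(grp$analysis_id, grp$id)

  from <- character(); to <- character()
  for (i in seq_len(nrow(grp))) {
    ins <- grp$input_file_ids[[i]]
    preds <- unique(producer[ins[ins %in% names(producer)]])
    b <- grp_analysis[[grp$id[i]]]
    preds <- setdiff(preds, b)
    if (length(preds) > 0L) { from <- c(from, preds); to <- c(to, rep(b, length(preds))) }
  }
  e <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  e <- e[order_c(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL

  # Kahn's algorithm with (execution_time, id) priority
  ids <- an$id
  prio <- order_c(an$execution_time, an$id)
  rank <- stats::setNames(match(seq_along(ids), prio), ids)  # smaller = earlier
  indeg <- stats::setNames(rep(0L, length(ids)), ids)
  if (nrow(e) > 0L) {
    tb <- table(e$to)
    indeg[names(tb)] <- as.integer(tb)
  }
  succ <- stats::setNames(vector("list", length(ids)), ids)
  if (nrow(e) > 0L) {
    sp <- split(e$to, e$from)
    succ[names(sp)] <- sp
  }
  out <- character(0)
  avail <- ids[indeg == 0L]
  while (length(avail) > 0L) {
    nxt <- avail[which.min(rank[avail])]
    out <- c(out, nxt)
    avail <- setdiff(avail, nxt)
    for (s in succ[[nxt]]) {
      indeg[[s]] <- indeg[[s]] - 1L
      if (indeg[[s]] == 0L) avail <- c(avail, s)
    }
  }
  if (length(out) != length(ids)) {
    stopf("cycle among analyses involving: %s",
          paste(setdiff(ids, out), collapse = ", "))
  }
  list(edges = e, order = out)
}

#' Input/output/group counts of an analysis
#'
#' Counts the distinct input files consumed over all of an analysis's groups,
#' the files it exposes as outputs, and its group count. A member file counts
#' as an output when it has no consumer inside the analysis, or when some
#' consumer lies outside the analysis (intermediate files consumed only
#' internally are not outputs).
#'
#' @param graph a valid `provenance_graph`.
#' @param analysis_id id of an existing analysis.
#' @return named list `n_inputs`, `n_outputs`, `n_groups` (integers).
#' @export
io_summary <- function(graph, analysis_id) {
  i <- match(analysis_id, graph$analyses$id)
  if (is.na(i)) stopf("unknown analysis id '%s'", analysis_id)
  gids <- graph$analyses$group_ids[[i]]
  gi <- match(gids, graph$groups$id)
  inputs <- unique(unlist(graph$groups$input_file_ids[gi], use.names = FALSE))
  members <- unlist(graph$groups$member_node_ids[gi], use.names = FALSE)
  kind <- node_kind_map(graph)
  files <- members[kind[members] == "FILE"]

  adj <- out_adjacency(graph)
  member_set <- members
  is_output <- vapply(files, function(f) {
    consumers <- adj[[f]] %||% character()
    internal <- sum(consumers %in% member_set)
    external <- length(consumers) - internal
    internal == 0L || external > 0L
  }, logical(1))
  list(n_inputs = length(inputs),
       n_outputs = sum(is_output),
       n_groups = length(gids))
}
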