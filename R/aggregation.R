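# Motif-based aggregation of analyses into layers, the per-layer change
# metric, and construction of the mixed-level display graph.
#
# A layer (AL3) merges analyses that share both a workflow template and an
# upstream provenance context. The context of an analysis is the set of layer
# ids already assigned to its direct predecessor analyses (ROOT when it has
# none), so two analyses that run the same template on differently-derived
# inputs land in different layers. Because an analysis's context can never
# contain its own layer, edges between layers always point from
# earlier-created to later-created layers and the layer quotient of a valid
# provenance DAG stays acyclic.

ROOT_CONTEXT <- "ROOT"

#' Assign analyses to motif-based layers
#'
#' Processes analyses in the deterministic topological order of
#' [analysis_dag()]. Each analysis joins (or creates) the layer keyed by its
#' workflow template and its provenance context. In the default mode the
#' context is the sorted set of layer ids of its direct predecessor analyses;
#' with `strict = TRUE` the context is the sorted set of all upstream layer
#' ids (full chains), a stronger separation.
#'
#' @param graph a valid `provenance_graph`.
#' @param strict use full upstream layer-id chains as context instead of
#'   direct predecessors only.
#' @return A data.frame of class `prov_layers` with columns `id`,
#'   `template_id`, list columns `context` and `members` (analysis ids
#'   ordered by `(execution_time, id)`), and attribute `layer_of`, a named
#'   character vector mapping analysis id to layer id.
#' @export
assign_layers <- function(graph, strict = FALSE) {
  dag <- analysis_dag(graph)
  an <- graph$analyses
  tmpl <- stats::setNames(an$template_id, an$id)

  preds <- stats::setNames(vector("list", nrow(an)), an$id)
  if (nrow(dag$edges) > 0L) {
    sp <- split(dag$edges$from, dag$edges$to)
    preds[names(sp)] <- sp
  }

  layer_of <- stats::setNames(character(nrow(an)), an$id)
  upstream <- stats::setNames(vector("list", nrow(an)), an$id)  # strict mode
  key_to_layer <- new.env(parent = emptyenv())
  layers <- list()

  for (a in dag$order) {
    p <- preds[[a]] %||% character()
    ctx_layers <- sort_c(unique(layer_of[p]))
    if (strict) {
      up <- sort_c(unique(c(ctx_layers,
                            unlist(upstream[p], use.names = FALSE))))
      upstream[[a]] <- up
      ctx <- up
    } else {
      ctx <- ctx_layers
    }
    if (length(ctx) == 0L) ctx <- ROOT_CONTEXT
    key <- paste(c(tmpl[[a]], ctx), collapse = "\x1f")
    lid <- key_to_layer[[key]]
    if (is.null(lid)) {
      lid <- sprintf("layer-%d", length(layers) + 1L)
      assign(key, lid, envir = key_to_layer)
      layers[[lid]] <- list(id = lid, template_id = tmpl[[a]],
                            context = ctx, members = character())
    }
    layers[[lid]]$members <- c(layers[[lid]]$members, a)
    layer_of[[a]] <- lid
  }

  time_of <- stats::setNames(an$execution_time, an$id)
  out <- df_from_cols(list(
    id = vapply(layers, `[[`, character(1), "id"),
    template_id = vapply(layers, `[[`, character(1), "template_id"),
    context = lapply(layers, `[[`, "context"),
    members = lapply(layers, function(l) {
      m <- l$members
      m[order_c(time_of[m], m)]
    })
  ))
  structure(out, class = c("prov_layers", "data.frame"), layer_of = layer_of)
}

#' @export
print.prov_layers <- function(x, ...) {
  cat(sprintf("<prov_layers> %d layer(s)\n", nrow(x)))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s: template %s, context [%s], %d member(s)%s\n",
                x$id[i], x$template_id[i],
                paste(x$context[[i]], collapse = ", "),
                length(x$members[[i]]),
                if (!is.null(x$delta_raw) && x$delta_raw[i] > 0) " *" else ""))
  }
  invisible(x)
}

#' Compute per-layer change deltas
#'
#' Inside each layer, every member analysis is compared to the member with
#' the earliest execution time (ties broken by id): the delta of a member is
#' `|n_inputs - n_inputs0| + |n_outputs - n_outputs0| + |n_groups -
#' n_groups0|`. The layer's raw delta is the maximum member delta, so a
#' single diverging re-run flags the whole layer; the normalized delta
#' rescales raw deltas by the global maximum across layers (0 everywhere when
#' nothing changed). A layer is flagged as changed (asterisk in renderings)
#' iff its raw delta is positive.
#'
#' @param layers output of [assign_layers()].
#' @param graph the `provenance_graph` the layers were computed from.
#' @return `layers` with added columns `member_deltas` (list of data.frames
#'   with `analysis_id`, `d_in`, `d_out`, `d_groups`, `delta`), `delta_raw`
#'   (integer) and `delta_norm` (in `[0, 1]`).
#' @export
compute_layer_deltas <- function(layers, graph) {
  counts <- lapply(stats::setNames(graph$analyses$id, graph$analyses$id),
                   function(a) io_summary(graph, a))
  member_deltas <- vector("list", nrow(layers))
  raw <- integer(nrow(layers))
  for (i in seq_len(nrow(layers))) {
    m <- layers$members[[i]]        # already ordered (execution_time, id)
    ref <- counts[[m[1]]]
    d_in <- vapply(m, function(a) abs(counts[[a]]$n_inputs - ref$n_inputs), integer(1))
    d_out <- vapply(m, function(a) abs(counts[[a]]$n_outputs - ref$n_outputs), integer(1))
    d_grp <- vapply(m, function(a) abs(counts[[a]]$n_groups - ref$n_groups), integer(1))
    member_deltas[[i]] <- data.frame(
      analysis_id = m, d_in = d_in, d_out = d_out, d_groups = d_grp,
      delta = d_in + d_out + d_grp,
      stringsAsFactors = FALSE, row.names = NULL
    )
    raw[i] <- if (length(m) > 0L) max(member_deltas[[i]]$delta) else 0L
  }
  gmax <- if (length(raw) > 0L) max(raw) else 0L
  layers$member_deltas <- member_deltas
  layers$delta_raw <- raw
  layers$delta_norm <- if (gmax == 0L) rep(0, length(raw)) else raw / gmax
  layers
}

#' Build the mixed-level display graph
#'
#' Projects the base provenance DAG onto one display node per visible entity,
#' according to a per-analysis aggregation level: at `AL0` an analysis shows
#' its individual tool/file nodes (annotated with their bounding box), at
#' `AL1` one node per analysis input group, at `AL2` a single analysis node,
#' and at `AL3` the analysis merges into its layer's node. Raw input files
#' are always individual display nodes. Extracted analyses are shown as their
#' own analysis node connected to their layer node by an `extraction` edge.
#' Display edges are the deduplicated quotient of the base edges under the
#' node mapping.
#'
#' @param graph a valid `provenance_graph`.
#' @param layers layers with deltas (see [compute_layer_deltas()]); plain
#'   [assign_layers()] output is accepted (deltas then default to 0).
#' @param level_map named character vector mapping every non-hidden analysis
#'   id to `"AL0"`, `"AL1"`, `"AL2"`, or `"AL3"`.
#' @param extracted analysis ids to extract next to their layer node.
#' @param hidden analysis ids removed from the view entirely.
#' @param drop_orphan_raw drop raw files whose every consumer is hidden.
#' @return An object of class `display_graph`: list with `nodes`, `edges`
#'   (column `kind`: `"flow"` or `"extraction"`), and `mapping` (named
#'   character, base node id -> display node id). Node columns carry the
#'   level, entity reference, child/base counts, time and delta annotations
#'   used by layout and rendering.
#' @export
induce_display <- function(graph, layers, level_map, extracted = character(),
                           hidden = character(), drop_orphan_raw = FALSE) {
  an <- graph$analyses
  visible <- setdiff(an$id, hidden)
  missing <- setdiff(visible, names(level_map))
  if (length(missing) > 0L) {
    stopf("level_map is missing analyses: %s", paste(missing, collapse = ", "))
  }
  if (is.null(layers$delta_raw)) {
    layers$delta_raw <- rep(0L, nrow(layers))
    layers$delta_norm <- rep(0, nrow(layers))
  }
  layer_of <- attr(layers, "layer_of")
  time_of <- stats::setNames(an$execution_time, an$id)
  tmpl_name <- stats::setNames(graph$templates$name, graph$templates$id)
  an_tmpl <- stats::setNames(an$template_id, an$id)

  group_of <- group_of_node_map(graph)
  owner_of <- analysis_of_node_map(graph)

  mapping <- character()      # base node id -> display id
  nodes <- list()
  add_node <- function(id, level, kind, entity_id, label, child_count,
                       total_base_count, sort_time, time_min, time_max,
                       delta_raw = 0L, delta_norm = 0, box = NA_character_,
                       extracted = FALSE) {
    nodes[[id]] <<- list(id = id, level = level, kind = kind,
                         entity_id = entity_id, label = label,
                         child_count = as.integer(child_count),
                         total_base_count = as.integer(total_base_count),
                         sort_time = sort_time, time_min = time_min,
                         time_max = time_max, delta_raw = as.integer(delta_raw),
                         delta_norm = delta_norm, box = box,
                         extracted = extracted, dimmed = FALSE,
                         highlighted = FALSE)
  }

  # raw files: always individual
  raw <- graph$nodes[graph$nodes$kind == "RAW", , drop = FALSE]
  out_adj <- out_adjacency(graph)
  for (i in seq_len(nrow(raw))) {
    rid <- raw$id[i]
    if (drop_orphan_raw) {
      consumers <- out_adj[[rid]] %||% character()
      owners <- unique(owner_of[consumers])
      if (length(consumers) > 0L && all(owners %in% hidden)) next
    }
    mapping[[rid]] <- paste0("n:", rid)
    add_node(paste0("n:", rid), "AL0", "RAW", rid, raw$label[i],
             0L, 1L, -Inf, NA_real_, NA_real_)
  }

  node_label <- stats::setNames(graph$nodes$label, graph$nodes$id)
  node_kind <- node_kind_map(graph)
  layer_members_visible <- stats::setNames(vector("list", nrow(layers)), layers$id)

  for (a in visible) {
    lev <- level_map[[a]]
    gids <- an$group_ids[[match(a, an$id)]]
    members_by_group <- graph$groups$member_node_ids[match(gids, graph$groups$id)]
    all_members <- unlist(members_by_group, use.names = FALSE)
    lname <- tmpl_name[[an_tmpl[[a]]]]
    if (lev == "AL0") {
      for (m in all_members) {
        mapping[[m]] <- paste0("n:", m)
        add_node(paste0("n:", m), "AL0", node_kind[[m]], m, node_label[[m]],
                 0L, 1L, time_of[[a]], time_of[[a]], time_of[[a]], box = a)
      }
    } else if (lev == "AL1") {
      for (j in seq_along(gids)) {
        gid <- gids[[j]]
        did <- paste0("g:", gid)
        for (m in members_by_group[[j]]) mapping[[m]] <- did
        add_node(did, "AL1", NA_character_, gid, lname,
                 length(members_by_group[[j]]), length(members_by_group[[j]]),
                 time_of[[a]], time_of[[a]], time_of[[a]])
      }
    } else if (lev == "AL2" || (lev == "AL3" && a %in% extracted)) {
      did <- paste0("a:", a)
      for (m in all_members) mapping[[m]] <- did
      add_node(did, "AL2", NA_character_, a, lname,
               length(gids), length(all_members),
               time_of[[a]], time_of[[a]], time_of[[a]],
               extracted = (lev == "AL3" && a %in% extracted))
      if (lev == "AL3" && a %in% extracted) {
        lid <- layer_of[[a]]
        layer_members_visible[[lid]] <- c(layer_members_visible[[lid]], a)
      }
    } else {  # AL3, merged into layer
      lid <- layer_of[[a]]
      did <- paste0("l:", lid)
      for (m in all_members) mapping[[m]] <- did
      layer_members_visible[[lid]] <- c(layer_members_visible[[lid]], a)
    }
  }

  # layer nodes: one per layer with >= 1 visible AL3 member
  extraction_edges <- list()
  for (i in seq_len(nrow(layers))) {
    lid <- layers$id[i]
    mem <- layer_members_visible[[lid]]
    if (is.null(mem) || length(mem) == 0L) next
    all_mem <- layers$members[[i]]
    base_count <- sum(vapply(all_mem, function(a) {
      gids <- an$group_ids[[match(a, an$id)]]
      length(unlist(graph$groups$member_node_ids[match(gids, graph$groups$id)],
                    use.names = FALSE))
    }, integer(1)))
    times <- time_of[mem]
    add_node(paste0("l:", lid), "AL3", NA_character_, lid,
             tmpl_name[[layers$template_id[i]]],
             length(all_mem), base_count,
             min(times), min(times), max(times),
             delta_raw = layers$delta_raw[i], delta_norm = layers$delta_norm[i])
    for (x in intersect(mem, extracted)) {
      extraction_edges[[length(extraction_edges) + 1L]] <-
        c(paste0("l:", lid), paste0("a:", x))
    }
  }

  # induced edges
  e <- graph$edges
  if (nrow(e) > 0L) {
    keep <- e$source %in% names(mapping) & e$target %in% names(mapping)
    ds <- unname(mapping[e$source[keep]])
    dt <- unname(mapping[e$target[keep]])
    nz <- ds != dt
    edges <- unique(data.frame(from = ds[nz], to = dt[nz], kind = "flow",
                               stringsAsFactors = FALSE))
  } else {
    edges <- data.frame(from = character(), to = character(), kind = character(),
                        stringsAsFactors = FALSE)
  }
  for (xe in extraction_edges) {
    edges <- rbind(edges, data.frame(from = xe[1], to = xe[2],
                                     kind = "extraction", stringsAsFactors = FALSE))
  }
  edges <- edges[order_c(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  if (length(nodes) == 0L) {
    nodes_df <- data.frame(id = character(), level = character(),
                           kind = character(), entity_id = character(),
                           label = character(), child_count = integer(),
                           total_base_count = integer(), sort_time = numeric(),
                           time_min = numeric(), time_max = numeric(),
                           delta_raw = integer(), delta_norm = numeric(),
                           box = character(), extracted = logical(),
                           dimmed = logical(), highlighted = logical(),
                           stringsAsFactors = FALSE)
  } else {
    fields <- names(nodes[[1]])
    nodes_df <- df_from_cols(stats::setNames(
      lapply(fields, function(cl) {
        unlist(lapply(nodes, `[[`, cl), use.names = FALSE)
      }),
      fields
    ))
  }
  nodes_df <- nodes_df[order_c(nodes_df$id), , drop = FALSE]
  rownames(nodes_df) <- NULL

  disp <- structure(
    list(nodes = nodes_df, edges = edges, mapping = mapping,
         time_range = if (nrow(an) > 0L) range(an$execution_time)
                      else c(NA_real_, NA_real_)),
    class = "display_graph"
  )
  cyc <- find_cycle(nodes_df$id,
                    data.frame(source = edges$from, target = edges$to,
                               stringsAsFactors = FALSE))
  if (!is.null(cyc)) {
    stopf("internal error: induced display graph contains a cycle: %s",
          paste(cyc, collapse = " -> "))
  }
  disp
}

#' @export
print.display_graph <- function(x, ...) {
  lv <- table(factor(x$nodes$level, levels = AGGREGATION_LEVELS))
  cat(sprintf("<display_graph> %d nodes (AL0 %d, AL1 %d, AL2 %d, AL3 %d), %d edges\n",
              nrow(x$nodes), lv[["AL0"]], lv[["AL1"]], lv[["AL2"]], lv[["AL3"]],
              nrow(x$edges)))
  invisible(x)
}
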