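# Column-based layered layout for display graphs.
#
# Columns come from longest-path layering (every edge points strictly to a
# later column), rows from a barycentric 2-layer crossing-reduction sweep
# seeded with (execution time, id) order, and coordinates from a spreadsheet
# model: the widest node in a column sets the column width, rows sit on a
# common grid, and a final centering pass pulls each node toward the mean y
# of its neighbors where that does not collide.

#' Node size model
#'
#' Abstract-unit widths and heights per aggregation level (and node kind at
#' AL0), plus the gaps between columns and rows.
#'
#' @param al0 width/height of workflow-instance glyphs.
#' @param al1,al2,al3 `c(width, height)` of group, analysis, and layer boxes.
#' @param col_gap,row_gap spacing between columns and rows.
#' @return object of class `size_model`.
#' @export
size_model <- function(al0 = c(26, 26), al1 = c(64, 36), al2 = c(84, 44),
                       al3 = c(104, 52), col_gap = 40, row_gap = 18) {
  dims <- list(AL0 = al0, AL1 = al1, AL2 = al2, AL3 = al3)
  for (d in dims) {
    if (length(d) != 2L || any(!is.finite(d)) || any(d <= 0)) {
      stopf("node sizes must be positive (width, height) pairs")
    }
  }
  if (col_gap <= 0 || row_gap <= 0) stopf("gaps must be positive")
  structure(c(dims, list(col_gap = col_gap, row_gap = row_gap)),
            class = "size_model")
}

node_sizes <- function(display, sizes) {
  dims <- t(vapply(display$nodes$level, function(lv) sizes[[lv]], numeric(2)))
  data.frame(id = display$nodes$id, width = dims[, 1], height = dims[, 2],
             stringsAsFactors = FALSE)
}

#' Assign display nodes to columns
#'
#' Longest-path layering: the column of a node is the length of the longest
#' directed path reaching it from any source, so every edge satisfies
#' `column(source) < column(target)`.
#'
#' @param display a `display_graph`.
#' @return named integer vector, display node id -> column (0-based).
#' @export
assign_columns <- function(display) {
  ids <- display$nodes$id
  col <- stats::setNames(rep(0L, length(ids)), ids)
  if (length(ids) == 0L) return(col)
  e <- display$edges
  topo <- display_topo_order(display)
  if (nrow(e) > 0L) {
    preds <- split(e$from, e$to)
    for (n in topo) {
      p <- preds[[n]]
      if (!is.null(p)) col[[n]] <- max(col[p]) + 1L
    }
  }
  col
}

# Deterministic topological order of a display graph (Kahn; ties by id).
display_topo_order <- function(display) {
  ids <- display$nodes$id
  e <- display$edges
  indeg <- stats::setNames(rep(0L, length(ids)), ids)
  if (nrow(e) > 0L) {
    tb <- table(e$to)
    indeg[names(tb)] <- as.integer(tb)
  }
  succ <- if (nrow(e) > 0L) split(e$to, e$from) else list()
  avail <- sort_c(ids[indeg == 0L])
  out <- character(0)
  while (length(avail) > 0L) {
    n <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, n)
    for (s in succ[[n]] %||% character()) {
      indeg[[s]] <- indeg[[s]] - 1L
      if (indeg[[s]] == 0L) avail <- sort_c(c(avail, s))
    }
  }
  if (length(out) != length(ids)) stopf("display graph contains a cycle")
  out
}

#' Count edge crossings between consecutive columns
#'
#' Two edges running between the same pair of consecutive columns cross when
#' their endpoints interleave. Exact brute-force count; edges spanning more
#' than one column are not counted (they are drawn as straight long
#' segments).
#'
#' @param display a `display_graph`.
#' @param columns output of [assign_columns()].
#' @param order list of character vectors: for each column (1-based index =
#'   column + 1), the node ids top to bottom.
#' @return integer crossing count.
#' @export
count_crossings <- function(display, columns, order) {
  e <- display$edges
  if (nrow(e) == 0L) return(0L)
  pos <- unlist(lapply(order, function(o) stats::setNames(seq_along(o), o)))
  total <- 0L
  span <- columns[e$to] - columns[e$from]
  for (c0 in sort(unique(columns[e$from]))) {
    sel <- columns[e$from] == c0 & span == 1L
    if (sum(sel) < 2L) next
    rs <- pos[e$from[sel]]
    rt <- pos[e$to[sel]]
    k <- sum(sel)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if ((rs[i] - rs[j]) * (rt[i] - rt[j]) < 0) total <- total + 1L
      }
    }
  }
  total
}

#' Order rows within columns by barycentric sweeps
#'
#' Starts from `(sort_time, id)` order within each column, then runs
#' alternating downward/upward 2-layer barycenter sweeps (a node moves to the
#' mean row of its adjacent-column neighbors; nodes without neighbors keep
#' their rank; ties keep the previous relative order). After each full sweep
#' the crossing count is measured and the best ordering seen is kept, so the
#' result never has more crossings than the initial order.
#'
#' @param display a `display_graph`.
#' @param columns output of [assign_columns()].
#' @param max_sweeps maximum number of full down+up sweeps (default 4).
#' @return list of character vectors (node ids per column, top to bottom).
#' @export
order_rows <- function(display, columns, max_sweeps = 4L) {
  nd <- display$nodes
  if (nrow(nd) == 0L) return(list())
  ncol_ <- max(columns) + 1L
  key_time <- stats::setNames(nd$sort_time, nd$id)
  order0 <- lapply(seq_len(ncol_) - 1L, function(cc) {
    ids <- nd$id[columns[nd$id] == cc]
    ids[order_c(key_time[ids], ids)]
  })
  e <- display$edges
  if (nrow(e) == 0L || ncol_ == 1L) return(order0)

  span <- columns[e$to] - columns[e$from]
  adj <- e[span == 1L, , drop = FALSE]
  best <- cur <- order0
  best_cross <- count_crossings(display, columns, cur)

  barysort <- function(ids, nbr_pos_of) {
    ranks <- seq_along(ids)
    bc <- vapply(seq_along(ids), function(i) {
      p <- nbr_pos_of(ids[i])
      if (length(p) == 0L) ranks[i] else mean(p)
    }, numeric(1))
    ids[order(bc)]  # stable: ties keep previous relative order
  }

  for (sweep in seq_len(max_sweeps)) {
    # downward: order column c by predecessors in c-1
    for (cc in seq_len(ncol_ - 1L)) {
      prev_pos <- stats::setNames(seq_along(cur[[cc]]), cur[[cc]])
      ids <- cur[[cc + 1L]]
      cur[[cc + 1L]] <- barysort(ids, function(n) {
        unname(prev_pos[adj$from[adj$to == n & adj$from %in% names(prev_pos)]])
      })
    }
    # upward: order column c by successors in c+1
    for (cc in rev(seq_len(ncol_ - 1L))) {
      next_pos <- stats::setNames(seq_along(cur[[cc + 1L]]), cur[[cc + 1L]])
      ids <- cur[[cc]]
      cur[[cc]] <- barysort(ids, function(n) {
        unname(next_pos[adj$to[adj$from == n & adj$to %in% names(next_pos)]])
      })
    }
    cross <- count_crossings(display, columns, cur)
    if (cross < best_cross) {
      best <- cur
      best_cross <- cross
    } else {
      break  # no improvement this sweep
    }
    if (best_cross == 0L) break
  }
  best
}

#' Assign grid coordinates
#'
#' Spreadsheet model: each column is as wide as its widest node plus the
#' column gap; `x` is the running sum of earlier column widths plus half the
#' node's own column width (column centers). `y` starts on a common row grid
#' (`row * (max node height + row gap)`), then one centering pass (in
#' topological column order) moves each node to the mean `y` of its graph
#' neighbors whenever that keeps all boxes in its column disjoint.
#'
#' @param display a `display_graph`.
#' @param columns output of [assign_columns()].
#' @param order output of [order_rows()].
#' @param sizes a [size_model()].
#' @return object of class `layout_result`: list with `nodes` (data.frame
#'   `id`, `column`, `row`, `x`, `y`, `width`, `height`), `col_widths`,
#'   `crossings`, `bbox` (total width/height).
#' @export
assign_coordinates <- function(display, columns, order, sizes = size_model()) {
  nd <- display$nodes
  sz <- node_sizes(display, sizes)
  rownames(sz) <- sz$id
  if (nrow(nd) == 0L) {
    return(structure(list(
      nodes = data.frame(id = character(), column = integer(), row = integer(),
                         x = numeric(), y = numeric(), width = numeric(),
                         height = numeric(), stringsAsFactors = FALSE),
      col_widths = numeric(), crossings = 0L, bbox = c(0, 0)
    ), class = "layout_result"))
  }
  ncol_ <- length(order)
  col_widths <- vapply(seq_len(ncol_), function(ci) {
    ids <- order[[ci]]
    if (length(ids) == 0L) return(sizes$col_gap)
    max(sz[ids, "width"]) + sizes$col_gap
  }, numeric(1))
  x_left <- cumsum(c(0, col_widths))[seq_len(ncol_)]

  row_h <- max(sz$height) + sizes$row_gap
  rows <- integer(nrow(nd)); names(rows) <- nd$id
  y <- numeric(nrow(nd)); names(y) <- nd$id
  for (ci in seq_len(ncol_)) {
    ids <- order[[ci]]
    rows[ids] <- seq_along(ids) - 1L
    y[ids] <- (seq_along(ids) - 1L) * row_h + sz[ids, "height"] / 2
  }
  # node centers sit mid-column with the gap trailing, so a lone node in the
  # first column centers at width/2
  x <- x_left[columns[nd$id] + 1L] +
    (col_widths[columns[nd$id] + 1L] - sizes$col_gap) / 2
  names(x) <- nd$id

  # one centering pass along topological order
  e <- display$edges
  if (nrow(e) > 0L) {
    nbrs <- stats::setNames(vector("list", nrow(nd)), nd$id)
    for (i in seq_len(nrow(e))) {
      nbrs[[e$from[i]]] <- c(nbrs[[e$from[i]]], e$to[i])
      nbrs[[e$to[i]]] <- c(nbrs[[e$to[i]]], e$from[i])
    }
    for (n in display_topo_order(display)) {
      nb <- nbrs[[n]]
      if (is.null(nb)) next
      target <- mean(y[nb])
      same_col <- setdiff(order[[columns[[n]] + 1L]], n)
      h_n <- sz[n, "height"]
      ok <- all(vapply(same_col, function(m) {
        abs(target - y[[m]]) >= (h_n + sz[m, "height"]) / 2 + sizes$row_gap / 2
      }, logical(1)))
      if (ok) y[[n]] <- target
    }
  }

  cross <- count_crossings(display, columns, order)
  nodes <- data.frame(
    id = nd$id,
    column = unname(columns[nd$id]),
    row = unname(rows[nd$id]),
    x = unname(x[nd$id]),
    y = unname(y[nd$id]),
    width = sz[nd$id, "width"],
    height = sz[nd$id, "height"],
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, col_widths = col_widths, crossings = cross,
                 bbox = c(sum(col_widths), max(nodes$y + nodes$height / 2))),
            class = "layout_result")
}

#' Layout a display graph
#'
#' Convenience wrapper running [assign_columns()], [order_rows()], and
#' [assign_coordinates()].
#'
#' @inheritParams assign_coordinates
#' @param max_sweeps passed to [order_rows()].
#' @return a `layout_result`.
#' @export
layout_display <- function(display, sizes = size_model(), max_sweeps = 4L) {
  columns <- assign_columns(display)
  order <- order_rows(display, columns, max_sweeps = max_sweeps)
  assign_coordinates(display, columns, order, sizes)
}
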