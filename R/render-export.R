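# Static visual encoding: deterministic SVG rendering of a laid-out display
# graph, plus DOT and GraphML structural export.
#
# Glyphs: diamonds for tools, squares for raw input data, circles for derived
# files; rectangles for aggregates, with a dashed outline and a
# white-to-black execution-time gradient for layers. Node brightness encodes
# age (white = earliest, black = most recent analysis). A layer whose change
# delta is positive carries an asterisk. Output is byte-stable: elements are
# emitted in sorted id order with fixed number formatting.

#' Rendering configuration
#'
#' @param dim_opacity opacity applied to dimmed (filtered-out, blend mode)
#'   nodes, in `(0, 1]`.
#' @param highlight_color stroke color for highlighted (traced) edges.
#' @param label_attr which node attribute to print under AL0 file glyphs
#'   (`"label"` uses the node label).
#' @param shade_light,shade_dark hex endpoints of the age ramp.
#' @return object of class `encoding_config`.
#' @export
encoding_config <- function(dim_opacity = 0.3, highlight_color = "#D95F02",
                            label_attr = "label",
                            shade_light = "#FFFFFF", shade_dark = "#000000") {
  if (!is_scalar_number(dim_opacity) || dim_opacity <= 0 || dim_opacity > 1) {
    stopf("dim_opacity must be in (0, 1]")
  }
  structure(list(dim_opacity = dim_opacity, highlight_color = highlight_color,
                 label_attr = label_attr, shade_light = shade_light,
                 shade_dark = shade_dark),
            class = "encoding_config")
}

#' Map an execution time to a gray shade
#'
#' Linear ramp over the observed time range: the earliest time maps to white
#' (`#FFFFFF`), the most recent to black (`#000000`). A degenerate range
#' (`t_min == t_max`) maps to white.
#'
#' @param t time(s) to shade, within `[t_min, t_max]`.
#' @param t_min,t_max range endpoints.
#' @return hex color string(s) like `"#808080"`.
#' @export
time_shade <- function(t, t_min, t_max) {
  if (any(t < t_min | t > t_max)) stopf("t outside [t_min, t_max]")
  f <- if (t_max == t_min) rep(0, length(t)) else (t - t_min) / (t_max - t_min)
  g <- as.integer(round(255 * (1 - f)))
  sprintf("#%02X%02X%02X", g, g, g)
}

# readable label color on a gray fill
contrast_color <- function(hex) {
  g <- strtoi(substr(hex, 2, 3), 16L)
  if (g < 128) "#FFFFFF" else "#000000"
}

num <- function(x) {
  # fixed formatting for byte-stable output
  sub("\\.?0+$", "", sprintf("%.2f", x))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# shared per-node render annotations (fill shade, badge, ...)
render_table <- function(display) {
  nd <- display$nodes
  tr <- display$time_range
  shade <- vapply(seq_len(nrow(nd)), function(i) {
    if (is.na(nd$time_min[i]) || is.na(tr[1])) return("#FFFFFF")
    time_shade(nd$time_min[i], tr[1], tr[2])
  }, character(1))
  shade_max <- vapply(seq_len(nrow(nd)), function(i) {
    if (is.na(nd$time_max[i]) || is.na(tr[1])) return("#FFFFFF")
    time_shade(nd$time_max[i], tr[1], tr[2])
  }, character(1))
  badge <- c(AL0 = "", AL1 = "G", AL2 = "A", AL3 = "L")[nd$level]
  data.frame(id = nd$id, shade = shade, shade_max = shade_max,
             badge = unname(badge), stringsAsFactors = FALSE)
}

#' Render a display graph to SVG
#'
#' One element per display node with its kind/level glyph: analysis-level
#' fills come from [time_shade()], layer nodes get a 2-stop gradient from
#' their earliest to their latest member shade, a dashed outline, and an
#' asterisk when their raw change delta is positive. Aggregate nodes print
#' their direct child count (layers additionally the total workflow-instance
#' count). Dimmed nodes are drawn at the configured opacity; highlighted
#' edges in the highlight color. Rendering the same inputs twice yields
#' byte-identical text.
#'
#' @param display a `display_graph`.
#' @param layout_result matching [layout_display()] output.
#' @param encoding an [encoding_config()].
#' @return SVG 1.1 document as a single string.
#' @export
to_svg <- function(display, layout_result, encoding = encoding_config()) {
  nd <- display$nodes
  ly <- layout_result$nodes
  missing <- setdiff(nd$id, ly$id)
  if (length(missing) > 0L) {
    stopf("layout is missing display nodes: %s", paste(missing, collapse = ", "))
  }
  rownames(ly) <- ly$id
  rt <- render_table(display)
  rownames(rt) <- rt$id
  pad <- 20
  w <- layout_result$bbox[1] + 2 * pad
  h <- layout_result$bbox[2] + 2 * pad
  if (nrow(nd) == 0L) { w <- 2 * pad; h <- 2 * pad }

  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
                   "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">"),
            num(w), num(h), num(w), num(h))
  )

  # gradient defs for layer nodes, sorted by id
  layer_ids <- sort_c(nd$id[nd$level == "AL3"])
  if (length(layer_ids) > 0L) {
    out <- c(out, "  <defs>")
    for (id in layer_ids) {
      out <- c(out, sprintf(
        paste0("    <linearGradient id=\"grad-%s\" x1=\"0\" y1=\"0\" x2=\"1\" y2=\"0\">",
               "<stop offset=\"0\" stop-color=\"%s\"/>",
               "<stop offset=\"1\" stop-color=\"%s\"/></linearGradient>"),
        xml_escape(id), rt[id, "shade"], rt[id, "shade_max"]))
    }
    out <- c(out, "  </defs>")
  }

  edge_key <- paste(display$edges$from, display$edges$to)
  hi <- attr(display, "highlighted_display_edges") %||% character()
  e_ord <- order_c(display$edges$from, display$edges$to)
  for (i in e_ord) {
    e <- display$edges[i, ]
    p1 <- ly[e$from, ]; p2 <- ly[e$to, ]
    is_hi <- paste(e$from, e$to) %in% hi
    style <- if (e$kind == "extraction") " stroke-dasharray=\"3,3\"" else ""
    col <- if (is_hi) encoding$highlight_color else "#999999"
    out <- c(out, sprintf(
      "  <line class=\"edge\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"%s\" stroke-width=\"%s\"%s/>",
      num(p1$x + pad + p1$width / 2), num(p1$y + pad),
      num(p2$x + pad - p2$width / 2), num(p2$y + pad),
      col, if (is_hi) "2.5" else "1", style))
  }

  for (id in sort_c(nd$id)) {
    i <- match(id, nd$id)
    p <- ly[id, ]
    cx <- p$x + pad; cy <- p$y + pad
    wd <- p$width; ht <- p$height
    fill <- rt[id, "shade"]
    opacity <- if (nd$dimmed[i]) sprintf(" opacity=\"%s\"", num(encoding$dim_opacity)) else ""
    lvl <- nd$level[i]
    g_open <- sprintf("  <g class=\"node %s\" id=\"%s\"%s>",
                      tolower(lvl), xml_escape(id), opacity)
    body <- character()
    if (lvl == "AL0") {
      kind <- nd$kind[i]
      if (kind == "TOOL") {
        body <- sprintf(
          "    <polygon points=\"%s,%s %s,%s %s,%s %s,%s\" fill=\"%s\" stroke=\"#333333\"/>",
          num(cx), num(cy - ht / 2), num(cx + wd / 2), num(cy),
          num(cx), num(cy + ht / 2), num(cx - wd / 2), num(cy), fill)
      } else if (kind == "RAW") {
        body <- sprintf(
          "    <rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\" stroke=\"#333333\"/>",
          num(cx - wd / 2), num(cy - ht / 2), num(wd), num(ht), fill)
      } else {
        body <- sprintf(
          "    <circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\" stroke=\"#333333\"/>",
          num(cx), num(cy), num(min(wd, ht) / 2), fill)
      }
      lab <- nd$label[i]
      body <- c(body, sprintf(
        "    <text x=\"%s\" y=\"%s\" font-size=\"8\" text-anchor=\"middle\">%s</text>",
        num(cx), num(cy + ht / 2 + 9), xml_escape(lab)))
      if (!is.na(nd$box[i])) {
        body <- c(body, sprintf(
          "    <rect class=\"bounding-box\" x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"none\" stroke=\"#BBBBBB\" data-analysis=\"%s\"/>",
          num(cx - wd / 2 - 3), num(cy - ht / 2 - 3), num(wd + 6), num(ht + 6),
          xml_escape(nd$box[i])))
      }
    } else {
      is_layer <- lvl == "AL3"
      fill_attr <- if (is_layer) sprintf("url(#grad-%s)", xml_escape(id)) else fill
      dash <- if (is_layer) " stroke-dasharray=\"5,3\"" else ""
      body <- sprintf(
        "    <rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\" stroke=\"#333333\"%s/>",
        num(cx - wd / 2), num(cy - ht / 2), num(wd), num(ht), fill_attr, dash)
      tcol <- contrast_color(rt[id, "shade"])
      counts <- if (is_layer) {
        sprintf("%d | %d", nd$child_count[i], nd$total_base_count[i])
      } else {
        sprintf("%d", nd$child_count[i])
      }
      body <- c(body, sprintf(
        "    <text x=\"%s\" y=\"%s\" font-size=\"9\" text-anchor=\"middle\" fill=\"%s\">[%s] %s (%s)</text>",
        num(cx), num(cy + 3), tcol, rt[id, "badge"],
        xml_escape(nd$label[i]), counts))
      if (is_layer && nd$delta_raw[i] > 0L) {
        body <- c(body, sprintf(
          "    <text class=\"delta-marker\" x=\"%s\" y=\"%s\" font-size=\"14\" text-anchor=\"middle\">*</text>",
          num(cx + wd / 2 - 6), num(cy - ht / 2 + 12)))
      }
    }
    out <- c(out, g_open, body, "  </g>")
  }
  out <- c(out, "</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Export a display graph as DOT or GraphML
#'
#' Structural export of the current view: display nodes carry their
#' aggregation level, node kind, child and base counts, age shade, and change
#' delta as typed attributes; edges are the deduplicated induced edges.
#' Output is deterministic (sorted ids) and parses with standard tooling
#' (Graphviz, igraph).
#'
#' @param display a `display_graph`.
#' @param format `"DOT"` or `"GraphML"`.
#' @return the document as a single string.
#' @export
export_graph <- function(display, format = c("DOT", "GraphML")) {
  if (length(format) == 1L && !(format %in% c("DOT", "GraphML"))) {
    stopf("unsupported export format '%s'", format)
  }
  format <- match.arg(format)
  nd <- display$nodes[order_c(display$nodes$id), , drop = FALSE]
  ed <- unique(display$edges[, c("from", "to", "kind")])
  ed <- ed[order_c(ed$from, ed$to), , drop = FALSE]
  rt <- render_table(display)
  rownames(rt) <- rt$id

  if (format == "DOT") {
    shape <- function(i) {
      switch(nd$level[i],
             AL0 = switch(nd$kind[i], TOOL = "diamond", RAW = "square", "circle"),
             "box")
    }
    lines <- c("digraph provenance {", "  rankdir=LR;")
    for (i in seq_len(nrow(nd))) {
      lines <- c(lines, sprintf(
        "  \"%s\" [label=\"%s\", shape=%s, level=\"%s\", kind=\"%s\", child_count=%d, total_base_count=%d, shade=\"%s\", delta=%s%s];",
        nd$id[i], gsub("\"", "\\\\\"", nd$label[i]), shape(i), nd$level[i],
        if (is.na(nd$kind[i])) "" else nd$kind[i],
        nd$child_count[i], nd$total_base_count[i], rt[nd$id[i], "shade"],
        num(nd$delta_norm[i]),
        if (nd$level[i] == "AL3") " , style=dashed" else ""))
    }
    for (i in seq_len(nrow(ed))) {
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [kind=\"%s\"];",
                                ed$from[i], ed$to[i], ed$kind[i]))
    }
    lines <- c(lines, "}")
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }

  # GraphML
  keydefs <- c(
    "  <key id=\"level\" for=\"node\" attr.name=\"level\" attr.type=\"string\"/>",
    "  <key id=\"kind\" for=\"node\" attr.name=\"kind\" attr.type=\"string\"/>",
    "  <key id=\"label\" for=\"node\" attr.name=\"label\" attr.type=\"string\"/>",
    "  <key id=\"child_count\" for=\"node\" attr.name=\"child_count\" attr.type=\"int\"/>",
    "  <key id=\"total_base_count\" for=\"node\" attr.name=\"total_base_count\" attr.type=\"int\"/>",
    "  <key id=\"shade\" for=\"node\" attr.name=\"shade\" attr.type=\"string\"/>",
    "  <key id=\"delta\" for=\"node\" attr.name=\"delta\" attr.type=\"double\"/>",
    "  <key id=\"edgekind\" for=\"edge\" attr.name=\"kind\" attr.type=\"string\"/>"
  )
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    keydefs,
    "  <graph id=\"provenance\" edgedefault=\"directed\">"
  )
  for (i in seq_len(nrow(nd))) {
    lines <- c(lines, sprintf("    <node id=\"%s\">", xml_escape(nd$id[i])),
               sprintf("      <data key=\"level\">%s</data>", nd$level[i]),
               sprintf("      <data key=\"kind\">%s</data>",
                       if (is.na(nd$kind[i])) "" else nd$kind[i]),
               sprintf("      <data key=\"label\">%s</data>", xml_escape(nd$label[i])),
               sprintf("      <data key=\"child_count\">%d</data>", nd$child_count[i]),
               sprintf("      <data key=\"total_base_count\">%d</data>", nd$total_base_count[i]),
               sprintf("      <data key=\"shade\">%s</data>", rt[nd$id[i], "shade"]),
               sprintf("      <data key=\"delta\">%s</data>", num(nd$delta_norm[i])),
               "    </node>")
  }
  for (i in seq_len(nrow(ed))) {
    lines <- c(lines, sprintf(
      "    <edge source=\"%s\" target=\"%s\"><data key=\"edgekind\">%s</data></edge>",
      xml_escape(ed$from[i]), xml_escape(ed$to[i]), ed$kind[i]))
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  paste0(paste(lines, collapse = "\n"), "\n")
}
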