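# Reading and writing the provenance document format.
#
# The document is a single self-describing JSON object (format
# "provdag-provenance", version 1) with explicit id cross-references between
# five arrays: nodes, edges, templates, groups, analyses. All arrays are
# sorted by id (edges by source, target) and attribute maps by key, so
# serializing the same graph twice yields byte-identical text. A schema
# describing the format ships in inst/extdata/provenance-schema.json.

PROV_FORMAT <- "provdag-provenance"
PROV_VERSION <- 1L

#' Load a provenance document
#'
#' Parses and validates a provenance-JSON document. Any invariant violation
#' (dangling reference, cycle, non-alternating edge, ...) raises an error
#' naming the offending entity.
#'
#' @param document JSON text (a string starting with `{`) or the path of a
#'   JSON file.
#' @return a validated [provenance_graph()].
#' @export
load_provenance <- function(document) {
  if (length(document) != 1L || !is.character(document)) {
    stopf("document must be a single JSON string or file path")
  }
  txt <- if (grepl("^\\s*\\{", document)) document else {
    if (!file.exists(document)) stopf("provenance file '%s' not found", document)
    paste(readLines(document, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) stopf("provenance document does not parse as JSON: %s",
                                            conditionMessage(e)))
  if (!identical(doc$format, PROV_FORMAT)) {
    stopf("unrecognized document format '%s' (expected '%s')",
          doc$format %||% "<missing>", PROV_FORMAT)
  }
  if (!identical(as.integer(doc$version %||% -1L), PROV_VERSION)) {
    stopf("unsupported document version '%s'", doc$version %||% "<missing>")
  }

  chr_or_na <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  req <- function(rec, field, what, id) {
    if (is.null(rec[[field]])) stopf("%s '%s' is missing required field '%s'",
                                     what, id %||% "<no id>", field)
    rec[[field]]
  }

  nodes <- rec_df(doc$nodes, function(r) {
    id <- req(r, "id", "node", r$id)
    list(id = as.character(id),
         kind = as.character(req(r, "kind", "node", id)),
         label = as.character(req(r, "label", "node", id)),
         group_id = chr_or_na(r$group_id),
         attrs = list(attr_map(r$attributes)))
  }, c("id", "kind", "label", "group_id"), "attrs")

  edges <- rec_df(doc$edges, function(r) {
    list(source = as.character(req(r, "source", "edge", NULL)),
         target = as.character(req(r, "target", "edge", NULL)))
  }, c("source", "target"), character())

  templates <- rec_df(doc$templates, function(r) {
    id <- req(r, "id", "template", r$id)
    list(id = as.character(id),
         name = as.character(req(r, "name", "template", id)),
         tool_names = list(as.character(unlist(req(r, "tool_names", "template", id)))),
         inputs_per_group = as.integer(req(r, "inputs_per_group", "template", id)),
         outputs_per_group = as.integer(req(r, "outputs_per_group", "template", id)))
  }, c("id", "name", "inputs_per_group", "outputs_per_group"), "tool_names")

  groups <- rec_df(doc$groups, function(r) {
    id <- req(r, "id", "group", r$id)
    list(id = as.character(id),
         analysis_id = as.character(req(r, "analysis_id", "group", id)),
         member_node_ids = list(as.character(unlist(r$member_node_ids))),
         input_file_ids = list(as.character(unlist(r$input_file_ids))))
  }, c("id", "analysis_id"), c("member_node_ids", "input_file_ids"))

  analyses <- rec_df(doc$analyses, function(r) {
    id <- req(r, "id", "analysis", r$id)
    list(id = as.character(id),
         template_id = as.character(req(r, "template_id", "analysis", id)),
         execution_time = as.numeric(req(r, "execution_time", "analysis", id)),
         group_ids = list(as.character(unlist(req(r, "group_ids", "analysis", id)))),
         user = chr_or_na(r$user))
  }, c("id", "template_id", "execution_time", "user"), "group_ids")

  provenance_graph(nodes, edges, templates, groups, analyses, validate = TRUE)
}

rec_df <- function(records, f, plain_cols, list_cols) {
  if (is.null(records) || length(records) == 0L) {
    out <- empty_df(plain_cols, list_cols)
    if ("execution_time" %in% plain_cols) out$execution_time <- numeric()
    if ("inputs_per_group" %in% plain_cols) {
      out$inputs_per_group <- integer(); out$outputs_per_group <- integer()
    }
    return(out)
  }
  rows <- lapply(records, f)
  cols <- names(rows[[1]])
  out <- stats::setNames(vector("list", length(cols)), cols)
  for (cl in cols) {
    vals <- lapply(rows, `[[`, cl)
    out[[cl]] <- if (cl %in% list_cols) lapply(vals, `[[`, 1L) else unlist(vals)
  }
  df_from_cols(out)
}

# data.frame from a list of equal-length columns, preserving list columns
df_from_cols <- function(cols) {
  n <- length(cols[[1]])
  out <- data.frame(row.names = seq_len(max(n, 0L)))
  for (nm in names(cols)) out[[nm]] <- cols[[nm]]
  rownames(out) <- NULL
  out
}

attr_map <- function(a) {
  if (is.null(a) || length(a) == 0L) return(stats::setNames(character(), character()))
  stats::setNames(vapply(a, as.character, character(1)), names(a))
}

#' Serialize a provenance graph
#'
#' Writes the canonical provenance-JSON document. Serialization is
#' deterministic: arrays sorted by id, attribute keys sorted, fixed field
#' order — so `save_provenance(load_provenance(x))` reproduces `x` byte for
#' byte, and two saves of the same graph are identical.
#'
#' @param graph a valid `provenance_graph`.
#' @param path optional file path; when given, the text is also written there.
#' @return the JSON document as a single string (invisibly when `path` is
#'   given).
#' @export
save_provenance <- function(graph, path = NULL) {
  v <- validate_graph(graph)
  if (nrow(v) > 0L) stopf("refusing to serialize an invalid graph (%d violations)", nrow(v))

  obj_list <- function(df, f) lapply(seq_len(nrow(df)), function(i) f(df[i, ]))
  named_or_empty <- function(x) {
    if (length(x) == 0L) structure(list(), names = character()) else as.list(x)
  }

  doc <- list(
    format = jsonlite::unbox(PROV_FORMAT),
    version = jsonlite::unbox(PROV_VERSION),
    nodes = obj_list(graph$nodes, function(r) {
      out <- list(id = jsonlite::unbox(r$id),
                  kind = jsonlite::unbox(r$kind),
                  label = jsonlite::unbox(r$label))
      if (!is.na(r$group_id)) out$group_id <- jsonlite::unbox(r$group_id)
      out$attributes <- named_or_empty(r$attrs[[1]])
      out
    }),
    edges = obj_list(graph$edges, function(r) {
      list(source = jsonlite::unbox(r$source), target = jsonlite::unbox(r$target))
    }),
    templates = obj_list(graph$templates, function(r) {
      list(id = jsonlite::unbox(r$id),
           name = jsonlite::unbox(r$name),
           tool_names = as.list(r$tool_names[[1]]),
           inputs_per_group = jsonlite::unbox(r$inputs_per_group),
           outputs_per_group = jsonlite::unbox(r$outputs_per_group))
    }),
    groups = obj_list(graph$groups, function(r) {
      list(id = jsonlite::unbox(r$id),
           analysis_id = jsonlite::unbox(r$analysis_id),
           member_node_ids = as.list(r$member_node_ids[[1]]),
           input_file_ids = as.list(r$input_file_ids[[1]]))
    }),
    analyses = obj_list(graph$analyses, function(r) {
      out <- list(id = jsonlite::unbox(r$id),
                  template_id = jsonlite::unbox(r$template_id),
                  execution_time = jsonlite::unbox(r$execution_time),
                  group_ids = as.list(r$group_ids[[1]]))
      if (!is.na(r$user)) out$user <- jsonlite::unbox(r$user)
      out
    })
  )
  txt <- as.character(jsonlite::toJSON(doc, pretty = 2, digits = NA, null = "list"))
  txt <- paste0(txt, "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
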