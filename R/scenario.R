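# Synthetic provenance generation.
#
# generate_chipseq() emits the provenance of a simulated multi-factor
# ChIP-seq study: 2 histone modifications x 2 tissues x 3 drug treatments x 2
# replicates = 24 raw sequencing files, run through five chained workflows
# (QC, Mapping, two peak callers MACS2 and SPP, and a Pileup/compression
# step) across multiple sessions, including a late re-run of MACS2 on a pair
# of files whose outputs are never consumed. The tools are provenance-level
# stand-ins: node labels use genomics file names but no sequence data exists.
# generate_random() produces randomized but always-valid provenance graphs as
# property-test fuel.

#' Scenario configuration
#'
#' Declarative description of the simulated ChIP-seq study. Defaults encode
#' the canonical design: 12 factor combinations, 2 replicates, 5 workflow
#' templates, a first session covering QC, Mapping, and the liver branch of
#' peak calling + pileup, a later session for the kidney branch, and a final
#' MACS2 re-run on one kidney file pair.
#'
#' @param modifications,tissues,treatments factor levels.
#' @param replicates replicates per factor combination (>= 1).
#' @param shapes per-workflow tool chains and output arities; a named list of
#'   `list(tools = <chr>, outputs = <int>)`. All templates take one input
#'   file per group.
#' @param session_times named numeric vector of epoch seconds: `session1`,
#'   `session2`, `rerun` (strictly increasing).
#' @param rerun `NULL` to disable, or a list with `workflow` (default
#'   `"MACS2"`), `tissue` (files re-run on, default `"kidney"`), and
#'   `n_files` (default 2).
#' @param seed integer recorded in the config; generation is fully
#'   deterministic given the config.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(modifications = c("H3K27ac", "H3K4me3"),
                            tissues = c("kidney", "liver"),
                            treatments = c("Alpha", "Beta", "Mock"),
                            replicates = 2L,
                            shapes = default_shapes(),
                            session_times = c(session1 = 1456820000,
                                              session2 = 1458030000,
                                              rerun = 1458640000),
                            rerun = list(workflow = "MACS2",
                                         tissue = "kidney", n_files = 2L),
                            seed = 1L) {
  if (length(modifications) == 0L || length(tissues) == 0L || length(treatments) == 0L) {
    stopf("factor level lists must be non-empty")
  }
  if (replicates < 1L) stopf("replicates must be >= 1")
  needed <- c("QC", "Mapping", "MACS2", "SPP", "Pileup")
  if (!all(needed %in% names(shapes))) {
    stopf("shapes must define all of: %s", paste(needed, collapse = ", "))
  }
  if (is.unsorted(session_times, strictly = TRUE)) {
    stopf("session times must be strictly increasing")
  }
  if (!is.null(rerun)) {
    rerun$workflow <- rerun$workflow %||% "MACS2"
    rerun$tissue <- rerun$tissue %||% tissues[1]
    rerun$n_files <- rerun$n_files %||% 2L
    if (!(rerun$tissue %in% tissues)) stopf("rerun tissue not among tissues")
  }
  structure(list(modifications = modifications, tissues = tissues,
                 treatments = treatments, replicates = as.integer(replicates),
                 shapes = shapes, session_times = session_times,
                 rerun = rerun, seed = as.integer(seed)),
            class = "scenario_config")
}

# Mapping has an internal intermediate file (two chained tools); the peak
# callers emit two peak files (narrow + region) per input.
default_shapes <- function() {
  list(
    QC      = list(tools = "fastqc",                    outputs = 1L),
    Mapping = list(tools = c("bowtie2", "samtools_sort"), outputs = 1L),
    MACS2   = list(tools = "macs2_callpeak",            outputs = 2L),
    SPP     = list(tools = "spp_peaks",                 outputs = 2L),
    Pileup  = list(tools = "bedtools_genomecov",        outputs = 1L)
  )
}

# mutable builder shared by both generators
new_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$nodes <- list(); b$edges <- list(); b$groups <- list(); b$analyses <- list()
  b
}

b_add_node <- function(b, id, kind, label, group_id = NA_character_,
                       attrs = character()) {
  b$nodes[[id]] <- list(id = id, kind = kind, label = label,
                        group_id = group_id, attrs = list(attrs))
}

b_add_edge <- function(b, s, t) {
  b$edges[[length(b$edges) + 1L]] <- c(s, t)
}

# One analysis: one group per input file, each group a linear tool/file chain
# per the template shape. Returns the ids of the exposed output files.
b_add_analysis <- function(b, aid, template_id, shape, input_ids, time,
                           attrs_of, user = NA_character_) {
  gids <- character(length(input_ids))
  outputs <- character(0)
  for (k in seq_along(input_ids)) {
    gid <- sprintf("%s-g%03d", aid, k)
    gids[k] <- gid
    inp <- input_ids[k]
    members <- character(0)
    base_attrs <- attrs_of[[inp]] %||% character()
    base_attrs <- base_attrs[setdiff(names(base_attrs), "file_name")]
    prev <- inp
    ntools <- length(shape$tools)
    for (ti in seq_len(ntools)) {
      tid <- sprintf("%s-t%d", gid, ti)
      b_add_node(b, tid, "TOOL", shape$tools[ti], gid)
      b_add_edge(b, prev, tid)
      members <- c(members, tid)
      if (ti < ntools) {
        fid <- sprintf("%s-f%d", gid, ti)
        fname <- sprintf("%s_step%d.tmp", gid, ti)
        b_add_node(b, fid, "FILE", fname, gid,
                   c(base_attrs, file_name = fname))
        b_add_edge(b, tid, fid)
        members <- c(members, fid)
        prev <- fid
      } else {
        for (oi in seq_len(shape$outputs)) {
          fid <- sprintf("%s-o%d", gid, oi)
          fname <- sprintf("%s_out%d.dat", gid, oi)
          b_add_node(b, fid, "FILE", fname, gid,
                     c(base_attrs, file_name = fname))
          b_add_edge(b, tid, fid)
          members <- c(members, fid)
          outputs <- c(outputs, fid)
          attrs_of[[fid]] <- c(base_attrs, file_name = fname)
        }
      }
    }
    b$groups[[gid]] <- list(id = gid, analysis_id = aid,
                            member_node_ids = list(members),
                            input_file_ids = list(inp))
  }
  b$analyses[[aid]] <- list(id = aid, template_id = template_id,
                            execution_time = time, group_ids = list(gids),
                            user = user)
  list(outputs = outputs, attrs_of = attrs_of)
}

b_build <- function(b, templates) {
  to_df <- function(recs, list_cols) {
    if (length(recs) == 0L) return(NULL)
    cols <- names(recs[[1]])
    df_from_cols(stats::setNames(lapply(cols, function(cl) {
      vals <- lapply(recs, `[[`, cl)
      if (cl %in% list_cols) lapply(vals, `[[`, 1L) else unlist(vals)
    }), cols))
  }
  nodes <- to_df(b$nodes, "attrs")
  edges <- if (length(b$edges) == 0L) NULL else {
    m <- do.call(rbind, b$edges)
    data.frame(source = m[, 1], target = m[, 2], stringsAsFactors = FALSE)
  }
  groups <- to_df(b$groups, c("member_node_ids", "input_file_ids"))
  analyses <- to_df(b$analyses, "group_ids")
  provenance_graph(nodes, edges, templates, groups, analyses)
}

#' Generate the simulated ChIP-seq study provenance
#'
#' Builds the full provenance graph of the default study design: raw files
#' annotated with their factor levels, QC and Mapping over all raw files in
#' session 1 together with the liver branch of peak calling (MACS2 + SPP) and
#' Pileup; the kidney branch in session 2; and (unless disabled) a MACS2
#' re-run on one pair of kidney files in a third session whose outputs are
#' left unconsumed. Generation is deterministic: the same config yields a
#' byte-identical provenance document.
#'
#' @param config a [scenario_config()].
#' @return list with `graph` (a `provenance_graph`) and `metadata`
#'   (data.frame, one row per raw file with its factor levels).
#' @export
generate_chipseq <- function(config = scenario_config()) {
  if (!inherits(config, "scenario_config")) stopf("config must be a scenario_config")
  sh <- config$shapes
  templates <- df_from_cols(list(
    id = paste0("wt-", tolower(names(sh))),
    name = names(sh),
    tool_names = lapply(sh, `[[`, "tools"),
    inputs_per_group = rep(1L, length(sh)),
    outputs_per_group = vapply(sh, function(s) as.integer(s$outputs), integer(1))
  ))
  tid <- stats::setNames(templates$id, templates$name)

  b <- new_builder()
  attrs_of <- list()

  # raw files, one per factor combination x replicate
  combos <- expand.grid(replicate = seq_len(config$replicates),
                        treatment = config$treatments,
                        tissue = config$tissues,
                        modification = config$modifications,
                        stringsAsFactors = FALSE)
  raw_ids <- character(nrow(combos))
  meta <- list()
  for (i in seq_len(nrow(combos))) {
    cm <- combos[i, ]
    rid <- sprintf("raw-%s-%s-%s-r%d", cm$modification, cm$tissue,
                   cm$treatment, cm$replicate)
    fname <- sprintf("chip_%s_%s_%s_rep%d.fastq", cm$modification, cm$tissue,
                     cm$treatment, cm$replicate)
    at <- c(modification = cm$modification, tissue = cm$tissue,
            treatment = cm$treatment, replicate = as.character(cm$replicate),
            file_name = fname)
    b_add_node(b, rid, "RAW", fname, attrs = at)
    attrs_of[[rid]] <- at
    raw_ids[i] <- rid
    meta[[i]] <- data.frame(id = rid, modification = cm$modification,
                            tissue = cm$tissue, treatment = cm$treatment,
                            replicate = cm$replicate, file_name = fname,
                            stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, meta)
  metadata <- metadata[order_c(metadata$id), , drop = FALSE]
  rownames(metadata) <- NULL

  st <- config$session_times
  run <- function(aid, wf, inputs, time) {
    if (length(inputs) == 0L) return(character(0))  # degenerate factor set
    res <- b_add_analysis(b, aid, tid[[wf]], sh[[wf]], inputs, time, attrs_of)
    attrs_of <<- res$attrs_of
    res$outputs
  }
  tissue_of <- function(ids) vapply(ids, function(x) attrs_of[[x]][["tissue"]],
                                    character(1))

  # session 1: QC + Mapping over everything, then the early tissue branch;
  # the study design processes liver early and kidney late
  late_tissue <- config$rerun$tissue %||% config$tissues[1]
  early <- setdiff(config$tissues, late_tissue)
  run("qc-s1", "QC", raw_ids, st[["session1"]])
  mapped <- run("mapping-s1", "Mapping", raw_ids, st[["session1"]] + 3600)

  early_mapped <- mapped[tissue_of(mapped) %in% early]
  late_mapped <- mapped[tissue_of(mapped) %in% late_tissue]
  peaks1 <- c(run("macs2-s1", "MACS2", early_mapped, st[["session1"]] + 7200),
              run("spp-s1", "SPP", early_mapped, st[["session1"]] + 10800))
  run("pileup-s1", "Pileup", peaks1, st[["session1"]] + 14400)

  # session 2: the late tissue branch
  peaks2 <- c(run("macs2-s2", "MACS2", late_mapped, st[["session2"]]),
              run("spp-s2", "SPP", late_mapped, st[["session2"]] + 3600))
  run("pileup-s2", "Pileup", peaks2, st[["session2"]] + 7200)

  # re-run: same template, same upstream context, outputs left unconsumed
  if (!is.null(config$rerun)) {
    pair <- late_mapped[seq_len(min(config$rerun$n_files, length(late_mapped)))]
    run("macs2-rerun", config$rerun$workflow, pair, st[["rerun"]])
  }

  list(graph = b_build(b, templates), metadata = metadata)
}

#' Generate a random valid provenance graph
#'
#' Property-test fuel: a random DAG of analyses, each with its own groups and
#' linear tool/file chains, where group inputs are drawn either from
#' previously produced files (with probability `p_chain`) or from fresh raw
#' files. Every output satisfies the full set of provenance invariants, and
#' the same seed reproduces the same graph.
#'
#' @param n_templates number of workflow templates (>= 1).
#' @param n_analyses number of analyses (0 gives a raw-only graph).
#' @param max_groups maximum groups per analysis.
#' @param max_tools maximum tool-chain length per template.
#' @param seed RNG seed.
#' @param p_chain probability that a group consumes a derived file.
#' @return a valid `provenance_graph`.
#' @export
generate_random <- function(n_templates = 3L, n_analyses = 10L, max_groups = 3L,
                            max_tools = 2L, seed = 1L, p_chain = 0.5) {
  if (n_templates < 1L) stopf("need at least one template")
  if (max_groups < 1L || max_tools < 1L) stopf("max_groups and max_tools must be >= 1")
  if (n_analyses < 0L) stopf("n_analyses must be >= 0")
  set.seed(seed)

  templates <- df_from_cols(list(
    id = sprintf("t%02d", seq_len(n_templates)),
    name = sprintf("wf_%02d", seq_len(n_templates)),
    tool_names = lapply(seq_len(n_templates), function(i) {
      sprintf("t%02d_tool%d", i, seq_len(sample.int(max_tools, 1L)))
    }),
    inputs_per_group = rep(1L, n_templates),
    outputs_per_group = sample(1:2, n_templates, replace = TRUE)
  ))

  b <- new_builder()
  attrs_of <- list()
  n_raw <- 0L
  new_raw <- function() {
    n_raw <<- n_raw + 1L
    rid <- sprintf("raw%03d", n_raw)
    b_add_node(b, rid, "RAW", paste0(rid, ".dat"),
               attrs = c(batch = as.character(sample.int(3L, 1L)),
                         file_name = paste0(rid, ".dat")))
    rid
  }
  if (n_analyses == 0L) {
    for (i in seq_len(max_groups)) new_raw()
    return(b_build(b, templates))
  }

  produced <- character(0)
  for (ai in seq_len(n_analyses)) {
    aid <- sprintf("a%03d", ai)
    tix <- sample.int(n_templates, 1L)
    shape <- list(tools = templates$tool_names[[tix]],
                  outputs = templates$outputs_per_group[tix])
    ng <- sample.int(max_groups, 1L)
    inputs <- vapply(seq_len(ng), function(k) {
      if (length(produced) > 0L && stats::runif(1) < p_chain) {
        sample(produced, 1L)
      } else {
        new_raw()
      }
    }, character(1))
    res <- b_add_analysis(b, aid, templates$id[tix], shape, inputs,
                          time = 1000 + ai, attrs_of)
    attrs_of <- res$attrs_of
    produced <- c(produced, res$outputs)
  }
  b_build(b, templates)
}

#' Export raw-file metadata as TSV
#'
#' One row per raw input file, one column per attribute name occurring on any
#' raw file (sorted), rows sorted by node id. A simplified stand-in for a
#' study metadata sheet.
#'
#' @param graph a valid `provenance_graph`.
#' @return TSV text (header always present) as a single string.
#' @export
export_metadata <- function(graph) {
  raw <- graph$nodes[graph$nodes$kind == "RAW", , drop = FALSE]
  attr_names <- sort_c(as.character(unique(unlist(lapply(raw$attrs, names)))))
  header <- paste(c("id", attr_names), collapse = "\t")
  if (nrow(raw) == 0L) return(paste0(header, "\n"))
  rows <- vapply(seq_len(nrow(raw)), function(i) {
    a <- raw$attrs[[i]]
    vals <- vapply(attr_names, function(nm) {
      if (nm %in% names(a)) a[[nm]] else ""
    }, character(1))
    paste(c(raw$id[i], vals), collapse = "\t")
  }, character(1))
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}
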