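# Layer assignment, change deltas, and display-graph induction.

test_that("a single analysis forms one layer with ROOT context", {
  g <- single_template_graph(3)
  ly <- assign_layers(g)
  expect_equal(nrow(ly), 1L)
  expect_equal(ly$context[[1]], "ROOT")
  expect_equal(ly$members[[1]], "a1")
})

test_that("same template on raw inputs shares a layer; chained copies split", {
  # two independent analyses of the same template -> identical keys
  g <- single_template_graph(2)
  g$groups$analysis_id <- c("a1", "a2")
  g$analyses <- rbind(g$analyses, g$analyses)
  g$analyses$id <- c("a1", "a2")
  g$analyses$execution_time <- c(1000, 2000)
  g$analyses$group_ids <- list("g01", "g02")
  g <- provenance_graph(g$nodes, g$edges, g$templates, g$groups, g$analyses)
  ly <- assign_layers(g)
  expect_equal(nrow(ly), 1L)
  expect_equal(ly$members[[1]], c("a1", "a2"))

  # one consuming the other's output -> contexts differ
  gc <- chained_graph(2)
  lyc <- assign_layers(gc)
  expect_equal(nrow(lyc), 2L)
  expect_equal(lyc$context[[1]], "ROOT")
  expect_equal(lyc$context[[2]], lyc$id[1])
})

test_that("strict mode separates analyses whose full upstream chains differ", {
  # a1(wtA) -> a2(wtB) -> a3(wtB): direct-predecessor contexts give a3 the
  # context {layer(a2)}; a4(wtB) fed by a raw-only wtB analysis cannot join
  g <- chained_graph(3, template_per_analysis = c("wtA", "wtB", "wtB"))
  ly <- assign_layers(g, strict = FALSE)
  lys <- assign_layers(g, strict = TRUE)
  # both modes: chaining the same template still separates by context here
  expect_equal(nrow(ly), 3L)
  expect_equal(nrow(lys), 3L)
  # strict contexts accumulate the whole upstream chain
  expect_equal(lys$context[[3]], sort(c(lys$id[1], lys$id[2]), method = "radix"))
})

test_that("layer delta follows the earliest-member difference rule", {
  # layer of identical analyses -> raw 0
  g <- single_template_graph(2)
  g$groups$analysis_id <- c("a1", "a2")
  g$analyses <- rbind(g$analyses, g$analyses)
  g$analyses$id <- c("a1", "a2")
  g$analyses$execution_time <- c(1000, 2000)
  g$analyses$group_ids <- list("g01", "g02")
  g <- provenance_graph(g$nodes, g$edges, g$templates, g$groups, g$analyses)
  ly <- compute_layer_deltas(assign_layers(g), g)
  expect_equal(ly$delta_raw, 0L)
  expect_equal(ly$delta_norm, 0)

  # counts (2,2,2) vs (4,4,4) -> member delta 6, raw 6
  g2 <- single_template_graph(6)
  g2$groups$analysis_id <- c("a1", "a1", "a2", "a2", "a2", "a2")
  g2$analyses <- rbind(g2$analyses, g2$analyses)
  g2$analyses$id <- c("a1", "a2")
  g2$analyses$execution_time <- c(1000, 2000)
  g2$analyses$group_ids <- list(c("g01", "g02"), c("g03", "g04", "g05", "g06"))
  g2 <- provenance_graph(g2$nodes, g2$edges, g2$templates, g2$groups, g2$analyses)
  ly2 <- compute_layer_deltas(assign_layers(g2), g2)
  expect_equal(nrow(ly2), 1L)
  md <- ly2$member_deltas[[1]]
  expect_equal(md$delta[md$analysis_id == "a1"], 0L)
  expect_equal(md$delta[md$analysis_id == "a2"], 6L)  # (4-2)+(4-2)+(4-2)
  expect_equal(ly2$delta_raw, 6L)
  expect_equal(ly2$delta_norm, 1)
})

test_that("the scenario re-run makes its layer the only changed one", {
  sc <- default_scenario()
  g <- sc$graph
  ly <- compute_layer_deltas(assign_layers(g), g)
  changed <- ly$id[ly$delta_raw > 0L]
  expect_length(changed, 1L)
  rerun_layer <- attr(ly, "layer_of")[["macs2-rerun"]]
  expect_equal(changed, rerun_layer)
  # the re-run landed in the same layer as the session MACS2 runs
  expect_equal(attr(ly, "layer_of")[["macs2-s1"]], rerun_layer)
  expect_equal(attr(ly, "layer_of")[["macs2-s2"]], rerun_layer)
  # delta recomputed independently from the document counts:
  # earliest member (macs2-s1) has 12 in / 24 out / 12 groups, the rerun 2/4/2
  expect_equal(ly$delta_raw[ly$id == rerun_layer], (12 - 2) + (24 - 4) + (12 - 2))
  expect_equal(ly$delta_norm[ly$id == rerun_layer], 1)
})

test_that("all-AL3 display holds one node per layer plus raw files", {
  g <- default_scenario()$graph
  ly <- compute_layer_deltas(assign_layers(g), g)
  lv <- stats::setNames(rep("AL3", nrow(g$analyses)), g$analyses$id)
  d <- induce_display(g, ly, lv)
  expect_equal(nrow(d$nodes), nrow(ly) + sum(g$nodes$kind == "RAW"))
  expect_equal(sum(d$edges$kind == "extraction"), 0L)
})

test_that("an AL0 analysis shows its base nodes verbatim with a bounding box", {
  g <- default_scenario()$graph
  ly <- compute_layer_deltas(assign_layers(g), g)
  lv <- stats::setNames(rep("AL3", nrow(g$analyses)), g$analyses$id)
  lv[["qc-s1"]] <- "AL0"
  d <- induce_display(g, ly, lv)
  qc_members <- unlist(g$groups$member_node_ids[g$groups$analysis_id == "qc-s1"])
  shown <- d$nodes[d$nodes$level == "AL0" & d$nodes$kind != "RAW", ]
  expect_setequal(shown$entity_id, qc_members)
  expect_true(all(shown$box == "qc-s1"))
})

test_that("induced edges equal the brute-force quotient on the scenario", {
  g <- default_scenario()$graph
  ly <- compute_layer_deltas(assign_layers(g), g)
  lv <- stats::setNames(rep("AL3", nrow(g$analyses)), g$analyses$id)
  d <- induce_display(g, ly, lv)
  expect_setequal(paste(d$edges$from, d$edges$to),
                  oracle_quotient(g$edges, al3_mapping(g, ly)))
})

test_that("extracted analyses keep their own node linked to the layer", {
  g <- default_scenario()$graph
  ly <- compute_layer_deltas(assign_layers(g), g)
  lv <- stats::setNames(rep("AL3", nrow(g$analyses)), g$analyses$id)
  d <- induce_display(g, ly, lv, extracted = "macs2-rerun")
  rerun_layer <- attr(ly, "layer_of")[["macs2-rerun"]]
  ex <- d$edges[d$edges$kind == "extraction", ]
  expect_equal(nrow(ex), 1L)
  expect_equal(ex$from, paste0("l:", rerun_layer))
  expect_equal(ex$to, "a:macs2-rerun")
  expect_true(d$nodes$extracted[d$nodes$id == "a:macs2-rerun"])
  # the rerun's base nodes map to the extracted node, not the layer
  expect_equal(unname(d$mapping[["macs2-rerun-g001-t1"]]), "a:macs2-rerun")
})

test_that("hiding analyses removes them and level_map gaps are an error", {
  g <- default_scenario()$graph
  ly <- compute_layer_deltas(assign_layers(g), g)
  lv <- stats::setNames(rep("AL3", nrow(g$analyses)), g$analyses$id)
  d <- induce_display(g, ly, lv, hidden = c("pileup-s1", "pileup-s2"))
  expect_false(any(grepl("^l:", d$nodes$id) &
                     d$nodes$entity_id == attr(ly, "layer_of")[["pileup-s1"]]))
  expect_error(induce_display(g, ly, lv[-1]), "missing analyses")
})

test_that("layer membership partitions analyses and co-members share context", {
  for (seed in 1:40) {
    g <- generate_random(n_templates = 2L, n_analyses = (seed %% 12L) + 1L,
                         max_groups = 2L, seed = seed, p_chain = 0.6)
    ly <- assign_layers(g)
    members <- unlist(ly$members, use.names = FALSE)
    expect_equal(sort(members, method = "radix"),
                 sort(g$analyses$id, method = "radix"))
    # co-members share template and predecessor-layer context (recomputed)
    dag <- analysis_dag(g)
    layer_of <- attr(ly, "layer_of")
    for (i in seq_len(nrow(ly))) {
      mem <- ly$members[[i]]
      expect_true(all(g$analyses$template_id[match(mem, g$analyses$id)] ==
                        ly$template_id[i]))
      ctxs <- vapply(mem, function(a) {
        p <- dag$edges$from[dag$edges$to == a]
        cx <- sort(unique(layer_of[p]), method = "radix")
        if (length(cx) == 0L) cx <- "ROOT"
        paste(cx, collapse = "|")
      }, character(1))
      expect_length(unique(ctxs), 1L)
      expect_equal(unname(ctxs[1]), paste(ly$context[[i]], collapse = "|"))
    }
  }
})

test_that("display graphs are deterministic across repeated construction", {
  g <- default_scenario()$graph
  ly <- compute_layer_deltas(assign_layers(g), g)
  lv <- stats::setNames(rep("AL3", nrow(g$analyses)), g$analyses$id)
  d1 <- induce_display(g, ly, lv)
  d2 <- induce_display(g, ly, lv)
  expect_identical(d1, d2)
  ly2 <- compute_layer_deltas(assign_layers(g), g)
  expect_identical(ly, ly2)
})
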