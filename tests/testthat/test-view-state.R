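# Filters, tracing, path-driven expansion, display resolution.

test_that("a pass-all filter flags everything and dims nothing", {
  g <- default_scenario()$graph
  st <- apply_filter(view_state(g), filter_spec())
  expect_setequal(st$flags$filter, g$analyses$id)
  expect_length(st$dimmed, 0L)
  expect_length(st$hidden, 0L)
})

test_that("facet filtering matches a recount from the metadata table", {
  sc <- default_scenario()
  g <- sc$graph
  st <- apply_filter(view_state(g),
                     filter_spec(facet = list(tissue = "kidney")))
  # expected: analyses with >= 1 group whose input file carries tissue=kidney;
  # recomputed from the metadata table + reachability, not from the filter code
  kidney_raws <- sc$metadata$id[sc$metadata$tissue == "kidney"]
  downstream <- oracle_reach(g$edges, kidney_raws, "DOWN")
  owner <- provdag:::analysis_of_node_map(g)
  expected <- unique(unname(owner[intersect(downstream, names(owner))]))
  expect_setequal(st$flags$filter, expected)
  # QC and Mapping consume kidney raws directly, liver-only branches do not
  expect_true(all(c("qc-s1", "mapping-s1", "macs2-s2") %in% st$flags$filter))
  expect_false("macs2-s1" %in% st$flags$filter)
})

test_that("BLEND only dims while HIDE removes analyses and orphan raws", {
  g <- default_scenario()$graph
  t2 <- g$analyses$execution_time[g$analyses$id == "macs2-s2"]
  spec_b <- filter_spec(time_range = c(t2, Inf), mode = "BLEND")
  st_b <- apply_filter(view_state(g), spec_b)
  res_b <- resolve_display(st_b, override_level = "AL3")
  base <- resolve_display(view_state(g), override_level = "AL3")
  expect_equal(nrow(res_b$display$nodes), nrow(base$display$nodes))
  expect_equal(res_b$display$edges[, c("from", "to")],
               base$display$edges[, c("from", "to")])
  expect_true(any(res_b$display$nodes$dimmed))

  spec_h <- filter_spec(time_range = c(t2, Inf), mode = "HIDE")
  st_h <- apply_filter(view_state(g), spec_h)
  res_h <- resolve_display(st_h, override_level = "AL3")
  # session-1-only layers (QC, Mapping, and nothing else that ran early) gone
  labs <- res_h$display$nodes$label
  expect_false("QC" %in% labs)
  expect_false("Mapping" %in% labs)
  expect_true(all(c("MACS2", "SPP", "Pileup") %in% labs))
  # HIDE equals inducing on the complement set
  ly <- st_h$layers
  lv <- stats::setNames(rep("AL3", nrow(g$analyses)), g$analyses$id)
  manual <- induce_display(g, ly, lv, hidden = st_h$hidden,
                           drop_orphan_raw = TRUE)
  expect_identical(res_h$display$nodes$id, manual$nodes$id)
  expect_identical(res_h$display$edges$from, manual$edges$from)
})

test_that("malformed filter ranges are rejected", {
  expect_error(filter_spec(time_range = c(10, 5)), "lo <= hi")
  expect_error(filter_spec(facet = list("x")), "named")
})

test_that("trace agrees with the exhaustive closure oracle on fixtures", {
  fixtures <- list(
    single_template_graph(4),
    chained_graph(3),
    generate_random(n_analyses = 6L, seed = 4L, p_chain = 0.7)
  )
  for (g in fixtures) {
    for (node in g$nodes$id) {
      for (dir in c("UP", "DOWN")) {
        got <- trace(g, node, dir)
        expect_equal(as.character(got), oracle_reach(g$edges, node, dir))
      }
    }
  }
})

test_that("tracing up from a raw input returns only itself", {
  g <- default_scenario()$graph
  up <- trace(g, "raw-H3K27ac-kidney-Alpha-r1", "UP")
  expect_equal(as.character(up), "raw-H3K27ac-kidney-Alpha-r1")
  expect_equal(nrow(attr(up, "edges")), 0L)
  expect_error(trace(g, "nope", "UP"), "unknown node")
})

test_that("a kidney raw file flows through both peak callers into pileup", {
  g <- default_scenario()$graph
  down <- trace(g, "raw-H3K27ac-kidney-Alpha-r1", "DOWN")
  owner <- provdag:::analysis_of_node_map(g)
  touched <- unique(unname(owner[intersect(down, names(owner))]))
  expect_true(all(c("macs2-s2", "spp-s2", "pileup-s2") %in% touched))
  # traced edge set: every edge with both endpoints in the closure
  e <- attr(down, "edges")
  expect_true(all(e$source %in% down & e$target %in% down))
})

test_that("expand_path highlights exactly the analyses owning traced nodes", {
  g <- default_scenario()$graph
  st <- expand_path(view_state(g), "raw-H3K27ac-kidney-Alpha-r1", "DOWN")
  owner <- provdag:::analysis_of_node_map(g)
  expected <- sort(unique(unname(owner[intersect(st$traced, names(owner))])),
                   method = "radix")
  expect_equal(st$flags$highlight, expected)
  expect_false("macs2-s1" %in% st$flags$highlight)

  # with all weight on HIGHLIGHT, traced analyses expand fully, others collapse
  st$weights <- doi_weights(c(HIGHLIGHT = 1), enabled = "HIGHLIGHT")
  res <- resolve_display(st)
  lvl <- stats::setNames(level_for_doi(unname(res$doi), st$config),
                         names(res$doi))
  expect_true(all(lvl[st$flags$highlight] == "AL0"))
  expect_true(all(lvl[setdiff(names(lvl), st$flags$highlight)] == "AL3"))
})

test_that("resolution is idempotent and honors SELECTED weight 1", {
  g <- default_scenario()$graph
  st <- view_state(g)
  r1 <- resolve_display(st)
  r2 <- resolve_display(st)
  expect_identical(r1$display, r2$display)
  expect_identical(r1$layout, r2$layout)
  expect_identical(r1$doi, r2$doi)

  st$weights <- doi_weights(c(SELECTED = 1), enabled = "SELECTED")
  st$flags$selected <- "pileup-s2"
  r <- resolve_display(st)
  expect_equal(unname(r$doi[["pileup-s2"]]), 1)
  expect_true(all(r$doi[setdiff(names(r$doi), "pileup-s2")] == 0))
  # the selected analysis is fully expanded, the rest collapsed into layers
  expect_true(any(r$display$nodes$box == "pileup-s2", na.rm = TRUE))
})

test_that("a single isolated analysis resolves to one layer plus raws", {
  g1 <- single_template_graph(3)
  st <- view_state(g1, weights = doi_weights(c(TIME = 1), enabled = "TIME"))
  r <- resolve_display(st)
  expect_equal(unname(r$doi[["a1"]]), 0)  # degenerate time range
  expect_equal(sum(r$display$nodes$level == "AL3"), 1L)
  expect_equal(nrow(r$display$nodes), 1L + 3L)
})

test_that("timeline bins aggregate input-group counts per day", {
  g <- default_scenario()$graph
  tb <- timeline_bins(g)
  expect_equal(sum(tb$n_analyses), nrow(g$analyses))
  expect_equal(sum(tb$n_groups), nrow(g$groups))
  expect_equal(nrow(tb), 3L)  # three separated sessions
  expect_true(all(tb$bin_end - tb$bin_start == 86400))
})

test_that("view-state JSON round-trips weights, flags, filter and trace", {
  g <- default_scenario()$graph
  st <- view_state(g, weights = set_weight(doi_weights(), "TIME", 0.4))
  st <- apply_filter(st, filter_spec(facet = list(tissue = "liver"),
                                     mode = "BLEND"))
  st <- expand_path(st, "raw-H3K27ac-liver-Mock-r1", "DOWN")
  st$flags$selected <- "macs2-s1"
  txt <- save_view_state(st)
  st2 <- load_view_state(g, txt)
  expect_equal(st2$weights$w, st$weights$w, tolerance = 1e-12)
  expect_equal(st2$flags, st$flags)
  expect_equal(st2$hidden, st$hidden)
  expect_equal(st2$dimmed, st$dimmed)
  expect_setequal(st2$traced, st$traced)
  r1 <- resolve_display(st); r2 <- resolve_display(st2)
  expect_identical(r1$display$nodes$id, r2$display$nodes$id)
  expect_identical(r1$doi, r2$doi)
})
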