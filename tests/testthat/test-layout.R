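# Layered layout: columns, crossing reduction, coordinates.

test_that("columns follow longest paths", {
  d <- mk_display(c("a", "b", "c"),
                  data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_equal(unname(assign_columns(d)[c("a", "b", "c")]), 0:2)

  dd <- mk_display(c("a", "b", "c", "d"),
                   data.frame(from = c("a", "a", "b", "c"),
                              to = c("b", "c", "d", "d")))
  expect_equal(unname(assign_columns(dd)[["d"]]), 2L)
})

test_that("scenario AL3 columns match the exhaustive longest-path oracle", {
  g <- default_scenario()$graph
  ly <- compute_layer_deltas(assign_layers(g), g)
  lv <- stats::setNames(rep("AL3", nrow(g$analyses)), g$analyses$id)
  d <- induce_display(g, ly, lv)
  cols <- assign_columns(d)
  e <- data.frame(source = d$edges$from, target = d$edges$to,
                  stringsAsFactors = FALSE)
  for (id in d$nodes$id) {
    expect_equal(unname(cols[[id]]), oracle_longest_path(e, id), info = id)
  }
  # raw files in column 0; QC/Mapping layers 1; peak callers 2; pileup 3
  name_of <- stats::setNames(d$nodes$label, d$nodes$id)
  expect_true(all(cols[grepl("^n:raw", names(cols))] == 0L))
  expect_equal(unname(cols[names(name_of)[name_of == "QC"]]), 1L)
  expect_equal(unname(cols[names(name_of)[name_of == "Mapping"]]), 1L)
  expect_equal(unname(cols[names(name_of)[name_of == "MACS2"]]), 2L)
  expect_equal(unname(cols[names(name_of)[name_of == "SPP"]]), 2L)
  expect_equal(unname(cols[names(name_of)[name_of == "Pileup"]]), 3L)
})

test_that("barycenter sweeps resolve the crossed 2x2 pattern and keep stability", {
  d0 <- mk_display(c("a1", "a2", "b1", "b2"),
                   data.frame(from = c("a1", "a2"), to = c("b1", "b2")))
  cols0 <- assign_columns(d0)
  ord0 <- order_rows(d0, cols0)
  expect_equal(count_crossings(d0, cols0, ord0), 0L)
  expect_equal(ord0[[1]], c("a1", "a2"))  # unchanged

  d1 <- mk_display(c("a1", "a2", "b1", "b2"),
                   data.frame(from = c("a1", "a2"), to = c("b2", "b1")))
  cols1 <- assign_columns(d1)
  expect_equal(count_crossings(d1, cols1,
                               list(c("a1", "a2"), c("b1", "b2"))), 1L)
  ord1 <- order_rows(d1, cols1)
  expect_equal(count_crossings(d1, cols1, ord1), 0L)

  # single column, no edges: initial (time, id) order retained
  ds <- mk_display(c("x", "y", "z"), NULL, times = c(3, 1, 2))
  expect_equal(order_rows(ds, assign_columns(ds))[[1]], c("y", "z", "x"))
})

test_that("crossing counts agree with the pairwise-inversion oracle", {
  set.seed(5)
  for (rep in 1:20) {
    nl <- sample(3:8, 1); nr <- sample(3:8, 1)
    left <- sprintf("l%02d", seq_len(nl))
    right <- sprintf("r%02d", seq_len(nr))
    ne <- sample(2:12, 1)
    e <- unique(data.frame(from = sample(left, ne, replace = TRUE),
                           to = sample(right, ne, replace = TRUE),
                           stringsAsFactors = FALSE))
    d <- mk_display(c(left, right), e)
    cols <- stats::setNames(c(rep(0L, nl), rep(1L, nr)), c(left, right))
    ord <- list(left, right)
    expect_equal(
      count_crossings(d, cols, ord),
      oracle_crossings(e, stats::setNames(seq_len(nl), left),
                       stats::setNames(seq_len(nr), right))
    )
  }
})

test_that("ordering never increases crossings and nears the bipartite optimum", {
  set.seed(17)
  for (rep in 1:12) {
    nl <- sample(4:7, 1); nr <- sample(4:7, 1)
    left <- sprintf("l%02d", seq_len(nl))
    right <- sprintf("r%02d", seq_len(nr))
    ne <- sample(4:14, 1)
    e <- unique(data.frame(from = sample(left, ne, replace = TRUE),
                           to = sample(right, ne, replace = TRUE),
                           stringsAsFactors = FALSE))
    d <- mk_display(c(left, right), e)
    cols <- assign_columns(d)
    # isolated right nodes may sit in column 0; keep the bipartite structure
    cols[left] <- 0L; cols[right] <- 1L
    init <- list(left, right)
    ord <- order_rows(d, cols)
    c_init <- count_crossings(d, cols, init)
    c_final <- count_crossings(d, cols, ord)
    expect_lte(c_final, c_init)
    opt <- oracle_min_crossings_right(e, ord[[1]], right)
    expect_lte(c_final, ceiling(1.5 * opt))
  }
})

test_that("coordinates: centering, column widths, and edge direction", {
  sm <- size_model()
  # single node centers at (w/2, h/2)
  d1 <- mk_display("solo", NULL)
  lr1 <- layout_display(d1, sm)
  expect_equal(lr1$nodes$x, sm$AL2[1] / 2)
  expect_equal(lr1$nodes$y, sm$AL2[2] / 2)

  # chain of three equal nodes aligns on one y
  d3 <- mk_display(c("a", "b", "c"),
                   data.frame(from = c("a", "b"), to = c("b", "c")))
  lr3 <- layout_display(d3, sm)
  expect_length(unique(lr3$nodes$y), 1L)
  expect_true(all(diff(lr3$nodes$x[match(c("a", "b", "c"), lr3$nodes$id)]) > 0))

  # a wide node dictates its column's width
  g <- default_scenario()$graph
  ly <- compute_layer_deltas(assign_layers(g), g)
  lv <- stats::setNames(rep("AL3", nrow(g$analyses)), g$analyses$id)
  d <- induce_display(g, ly, lv)
  lr <- layout_display(d, sm)
  cols <- assign_columns(d)
  for (ci in seq_along(lr$col_widths)) {
    ids <- names(cols)[cols == ci - 1L]
    wmax <- max(lr$nodes$width[match(ids, lr$nodes$id)])
    expect_equal(lr$col_widths[ci], wmax + sm$col_gap)
  }
  # all edges strictly left-to-right
  xs <- stats::setNames(lr$nodes$x, lr$nodes$id)
  expect_true(all(xs[d$edges$to] > xs[d$edges$from]))
})

test_that("node boxes never overlap on random display graphs", {
  set.seed(23)
  for (rep in 1:10) {
    g <- generate_random(n_analyses = sample(3:10, 1), seed = rep,
                         p_chain = 0.6)
    st <- view_state(g)
    res <- resolve_display(st)
    nd <- res$layout$nodes
    if (nrow(nd) < 2L) next
    for (i in seq_len(nrow(nd) - 1L)) {
      for (j in (i + 1L):nrow(nd)) {
        sep_x <- abs(nd$x[i] - nd$x[j]) >= (nd$width[i] + nd$width[j]) / 2
        sep_y <- abs(nd$y[i] - nd$y[j]) >= (nd$height[i] + nd$height[j]) / 2
        expect_true(sep_x || sep_y,
                    info = sprintf("seed %d: %s vs %s", rep, nd$id[i], nd$id[j]))
      }
    }
  }
})
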