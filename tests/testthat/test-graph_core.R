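test_that("edge lists parse with weights, loop dropping and dedup", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t2", "b\tc\t3", "a\tc\t1"), f)
  g <- read_edge_list(f)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(sum(igraph::E(g)$weight), 6)

  writeLines(c("a\ta\t5", "a\tb\t1"), f)
  expect_warning(g2 <- read_edge_list(f), "self-loop")
  expect_equal(igraph::vcount(g2), 2)

  writeLines(c("# comment", "a\tb\t1", "b\ta\t4"), f)
  expect_warning(g3 <- read_edge_list(f), "duplicate")
  expect_equal(igraph::E(g3)$weight, 1)  # first occurrence kept

  writeLines(character(0), f)
  expect_equal(igraph::vcount(read_edge_list(f)), 0)

  writeLines(c("a\tb\t1", "b\tc\t-2"), f)
  expect_error(read_edge_list(f), "line 2")
  writeLines(c("a\tb\tfoo"), f)
  expect_error(read_edge_list(f), "non-numeric")
})

test_that("cover files use the canonical order and round-trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_cover(list(c("b", "a"), c("d", "b", "c")), f)
  expect_equal(readLines(f), c("b c d", "a b"))
  write_cover(list("x"), f)
  expect_equal(readLines(f), "x")
  cov <- list(c("a", "b", "c"), c("c", "d"), "e")
  write_cover(cov, f)
  back <- read_cover(f)
  expect_setequal(vapply(back, paste, "", collapse = " "),
                  vapply(cov, function(x) paste(sort(x), collapse = " "), ""))
})

test_that("graphml round-trips a weighted graph", {
  f <- withr::local_tempfile(fileext = ".graphml")
  g <- unit_triangle(c(1.5, 2, 2.5))
  write_graphml(g, f)
  g2 <- read_graphml(f)
  expect_setequal(igraph::V(g2)$name, c("a", "b", "c"))
  expect_equal(sort(igraph::E(g2)$weight), c(1.5, 2, 2.5))
})

test_that("bridge decomposition separates 2-edge-connected components", {
  # two triangles joined by one bridge
  g <- gdf(c("a", "b", "a", "d", "e", "d", "c"),
           c("b", "c", "c", "e", "f", "f", "d"))
  dec <- bridge_decomposition(g)
  expect_length(dec$components, 2)
  expect_equal(nrow(dec$bridges), 1)
  expect_setequal(as.vector(dec$bridges), c("c", "d"))
  expect_equal(sort(vapply(dec$components, igraph::vcount, numeric(1))),
               c(3, 3))

  tree <- gdf(c("a", "b", "c"), c("b", "c", "d"))
  dtree <- bridge_decomposition(tree)
  expect_length(dtree$components, 0)
  expect_equal(nrow(dtree$bridges), 3)
  expect_setequal(dtree$residual_nodes, c("a", "b", "c", "d"))
})

test_that("bridge sets match the remove-and-test oracle on random graphs", {
  set.seed(11)
  for (i in 1:25) {
    g <- random_graph(sample(5:9, 1), p = 0.3)
    if (igraph::ecount(g) == 0) next
    dec <- bridge_decomposition(g)
    want <- oracle_bridges(g)
    key <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
    expect_equal(key(dec$bridges), key(want))
    # no component contains a bridge of its own
    for (comp in dec$components)
      expect_equal(nrow(oracle_bridges(comp)), 0)
  }
})

test_that("weight normalization maps affinely onto [1, s]", {
  g <- unit_triangle(c(2, 2, 2))
  expect_equal(igraph::E(normalize_weights(g, 4))$weight, c(1, 1, 1))
  g2 <- gdf(c("a", "b"), c("b", "c"), c(1, 3))
  expect_equal(sort(igraph::E(normalize_weights(g2, 3))$weight), c(1, 3))
  g3 <- gdf(c("a", "b", "c"), c("b", "c", "a"), c(10, 20, 30))
  expect_equal(sort(igraph::E(normalize_weights(g3, 2))$weight), c(1, 1.5, 2))
  # idempotent for fixed s
  g4 <- normalize_weights(g3, 7)
  expect_equal(igraph::E(normalize_weights(g4, 7))$weight,
               igraph::E(g4)$weight)
  expect_error(normalize_weights(g3, 0.5), "s must be")
})

test_that("trade graph construction thresholds and symmetrizes", {
  flows <- data.frame(
    from = c("A", "A", "B", "B"), to = c("B", "C", "A", "D"),
    weight = c(10, 90, 10, 90))
  g <- build_undirected_trade_graph(flows, 0.05, normalize = "out")
  e <- igraph::as_edgelist(g)
  i <- which((e[, 1] == "A" & e[, 2] == "B") | (e[, 1] == "B" & e[, 2] == "A"))
  expect_equal(igraph::E(g)$weight[i], 0.10)

  # one direction at 4% (below threshold), reverse at 8%: kept at the mean
  flows2 <- data.frame(
    from = c("A", "A", "B", "B"), to = c("B", "C", "A", "D"),
    weight = c(4, 96, 8, 92))
  g2 <- build_undirected_trade_graph(flows2, 0.05, normalize = "out")
  e2 <- igraph::as_edgelist(g2)
  i2 <- which((e2[, 1] == "A" & e2[, 2] == "B") |
                (e2[, 1] == "B" & e2[, 2] == "A"))
  expect_equal(igraph::E(g2)$weight[i2], 0.06)

  # everything below threshold: empty graph
  flows3 <- data.frame(from = c("A", "A", "A", "A", "A"),
                       to = c("B", "C", "D", "E", "F"),
                       weight = rep(1, 5))
  g3 <- build_undirected_trade_graph(flows3, 0.5, normalize = "out")
  expect_equal(igraph::ecount(g3), 0)
})
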