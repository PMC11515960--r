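test_that("closed-trail distances on canonical small graphs", {
  tri <- unit_triangle()
  expect_equal(wct_distance(tri, "a", "b", use_weights = FALSE), 3)
  tri2 <- unit_triangle(c(2, 2, 2))
  expect_equal(wct_distance(tri2, "a", "b"), 1.5)

  ring5 <- igraph::make_ring(5)
  igraph::V(ring5)$name <- letters[1:5]
  D5 <- wct_matrix(ring5, use_weights = FALSE)
  expect_true(all(D5[upper.tri(D5)] == 5))

  bow <- bowtie_graph()  # shared cut vertex, no bridge: still finite
  expect_equal(wct_distance(bow, "a", "d", use_weights = FALSE), 6)

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  D <- wct_matrix(k4, use_weights = FALSE)
  expect_true(all(D[upper.tri(D)] == 3))
  expect_true(all(diag(D) == 0))

  expect_error(wct_distance(tri, "a", "a"), "distinct")
})

test_that("suurballe finds minimum-cost edge-disjoint path pairs", {
  sq <- gdf(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
  res <- suurballe_pair(sq, "a", "c")
  expect_equal(res$cost, 4)
  e1 <- paste(head(res$paths[[1]], -1), res$paths[[1]][-1])
  e2 <- paste(head(res$paths[[2]], -1), res$paths[[2]][-1])
  expect_length(intersect(e1, e2), 0)

  # trap: the single shortest path s-u-v-t blocks both disjoint paths
  trap <- gdf(c("s", "u", "s", "v", "u"), c("u", "t", "v", "t", "v"),
              c(1, 10, 10, 1, 1))
  res2 <- suurballe_pair(trap, "s", "t",
                         edge_cost = igraph::E(trap)$weight)
  expect_equal(res2$cost, 22)  # forced onto s-u-t and s-v-t

  # endpoints joined only through a bridge: infeasible
  br <- gdf(c("a", "b", "a", "c", "d", "c"),
            c("b", "x", "x", "d", "y", "y"))
  br <- igraph::add_edges(br, c("x", "c"))
  expect_false(suurballe_pair(br, "a", "d")$feasible)
  expect_equal(wct_distance(br, "a", "d"), Inf)
})

test_that("closed-trail distance structural properties hold", {
  set.seed(21)
  for (i in 1:12) {
    g <- random_2ec_graph(sample(5:8, 1))
    D <- wct_matrix(g, use_weights = FALSE)
    expect_equal(D, t(D))
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    off <- upper.tri(D)
    # adjacent pairs need >= 3 edges in a closed trail, nonadjacent >= 4
    expect_true(all(D[off & A > 0] >= 3))
    expect_true(all(D[off & A == 0] >= 4))
    # with unit weights the weighted mode agrees exactly
    g1 <- g; igraph::E(g1)$weight <- 1
    expect_equal(wct_matrix(g1, use_weights = TRUE), D)
    # adding an edge never increases any entry
    nonadj <- which(A == 0 & off, arr.ind = TRUE)
    if (nrow(nonadj) > 0) {
      pick <- nonadj[1, ]
      g2 <- igraph::add_edges(g, igraph::V(g)$name[pick],
                              attr = list(weight = 1))
      D2 <- wct_matrix(g2, use_weights = FALSE)
      expect_true(all(D2 <= D + 1e-12))
    }
  }
})

test_that("distances equal the exhaustive closed-trail oracle", {
  set.seed(31)
  for (i in 1:20) {
    g <- random_2ec_graph(sample(5:8, 1))
    if (igraph::ecount(g) > 16) next
    D <- wct_matrix(g)
    labs <- igraph::V(g)$name
    for (u in seq_along(labs)[-1]) for (v in seq_len(u - 1)) {
      expect_equal(D[u, v], oracle_wct(g, labs[u], labs[v]),
                   tolerance = 1e-9)
    }
  }
})

test_that("distance matrices dump as TSV with labels", {
  f <- withr::local_tempfile(fileext = ".tsv")
  D <- wct_matrix(unit_triangle(), use_weights = FALSE)
  write_distance_matrix(D, f)
  back <- as.matrix(read.table(f, sep = "\t", header = TRUE, row.names = 1))
  expect_equal(unname(back), unname(D))
})
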