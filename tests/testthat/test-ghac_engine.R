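test_that("dissimilarities match the printed formulas", {
  bow <- bowtie_graph()
  D <- wct_matrix(bow, use_weights = FALSE)
  # disjoint clusters: plain linkage on closed-trail distances
  expect_equal(dissimilarity_cl(bow, D, c("a", "b"), c("d", "e")),
               max(D[c("a", "b"), c("d", "e")]))
  expect_equal(dissimilarity_al(bow, D, c("a", "b"), c("d", "e")),
               sum(D[c("a", "b"), c("d", "e")]) / 4)
  # nested clusters collapse to zero
  expect_equal(dissimilarity_cl(bow, D, c("a", "b"), c("a", "b", "c")), 0)
  expect_equal(dissimilarity_al(bow, D, c("a", "b", "c"), c("b", "c")), 0)
  # uniform cross distances: AL equals that distance
  d <- D["a", "d"]
  expect_equal(dissimilarity_al(bow, D, c("a", "b"), c("d", "e")), d)

  # overlapping clusters: against direct evaluation of the formula
  set.seed(61)
  for (i in 1:10) {
    g <- random_2ec_graph(sample(6:8, 1))
    Dg <- wct_matrix(g)
    labs <- igraph::V(g)$name
    a <- sample(labs, sample(3:4, 1))
    b <- sample(labs, sample(3:4, 1))
    if (setequal(a, b)) next
    expect_equal(dissimilarity_cl(g, Dg, a, b),
                 oracle_dissimilarity(g, Dg, a, b, "cl"), tolerance = 1e-12)
    expect_equal(dissimilarity_al(g, Dg, a, b),
                 oracle_dissimilarity(g, Dg, a, b, "al"), tolerance = 1e-12)
  }
})

test_that("agglomeration merges greedily and deterministically", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  dend <- agglomerate(k4)
  expect_equal(nrow(dend$merges), 0)  # single clique, nothing to merge

  # two triangles in a 2-edge-connected shell
  g <- gdf(c("a", "b", "a", "d", "e", "d", "c", "f"),
           c("b", "c", "c", "e", "f", "f", "d", "a"))
  dend2 <- agglomerate(g, linkage = "al", use_weights = FALSE)
  expect_equal(nrow(dend2$merges), length(dend2$base) - 1)
  expect_true(all(dend2$merges$height >= 0))

  set.seed(71)
  g3 <- random_2ec_graph(9, p = 0.5)
  d1 <- agglomerate(g3, linkage = "al")
  d2 <- agglomerate(g3, linkage = "al")
  expect_identical(d1$merges, d2$merges)
})

test_that("level covers filter, deduplicate and fill", {
  g <- gdf(c("a", "b", "a", "d", "e", "d", "c", "f"),
           c("b", "c", "c", "e", "f", "f", "d", "a"))
  dend <- agglomerate(g, use_weights = FALSE)
  cov0 <- cover_at_level(dend, 0, min_size = 1, fill = FALSE, g = g)
  expect_equal(length(cov0), length(dend$base))
  expect_error(cover_at_level(dend, 99, g = g), "level")

  # min_size filters everything out: empty cover, not an error
  cov_empty <- cover_at_level(dend, 0, min_size = 7, fill = FALSE, g = g)
  expect_length(cov_empty, 0)

  # final level covers the whole component
  covL <- cover_at_level(dend, nrow(dend$merges), min_size = 1,
                         fill = FALSE, g = g)
  expect_setequal(unlist(covL), igraph::V(g)$name)

  # fill attaches an uncovered vertex to its strongest neighbourhood
  gf <- gdf(c("a", "b", "a", "x", "x", "c", "d", "c", "b"),
            c("b", "c", "c", "a", "b", "d", "e", "e", "d"),
            c(1, 1, 1, 3, 3, 1, 1, 1, 1))
  cover <- fill_result <- cover_at_level(
    agglomerate(gf), 0, min_size = 3, fill = TRUE, g = gf)
  expect_true("x" %in% unlist(cover))
})

test_that("cliques are never split across communities", {
  set.seed(81)
  g <- random_2ec_graph(10, 0.55)
  dend <- agglomerate(g)
  cl <- dend$base
  for (lev in c(0, nrow(dend$merges) %/% 2, nrow(dend$merges))) {
    cov <- cover_at_level(dend, lev, min_size = 1, fill = FALSE, g = g)
    for (q in cl)
      expect_true(any(vapply(cov, function(cm) all(q %in% cm), TRUE)))
  }
})

test_that("detection recovers planted structure end to end", {
  # complete graph: one clique, one community
  k8 <- igraph::make_full_graph(8)
  igraph::V(k8)$name <- paste0("v", 1:8)
  res <- detect_communities(k8, min_size = 5)
  expect_length(res$cover, 1)
  expect_setequal(res$cover[[1]], paste0("v", 1:8))

  # two 6-cliques joined by a sparse 2-edge-connected frame
  c1 <- t(utils::combn(paste0("a", 1:6), 2))
  c2 <- t(utils::combn(paste0("b", 1:6), 2))
  frame <- rbind(c("a1", "b1"), c("a2", "b2"))
  g <- gdf(c(c1[, 1], c2[, 1], frame[, 1]),
           c(c1[, 2], c2[, 2], frame[, 2]))
  res2 <- detect_communities(g, min_size = 5, fill = TRUE)
  expect_length(res2$cover, 2)
  expect_true(any(vapply(res2$cover, function(cm)
    all(paste0("a", 1:6) %in% cm), TRUE)))
  expect_true(any(vapply(res2$cover, function(cm)
    all(paste0("b", 1:6) %in% cm), TRUE)))

  # a tree has no 2-edge-connected component: empty result, no crash
  tree <- gdf(c("a", "b", "c"), c("b", "c", "d"))
  res3 <- detect_communities(tree)
  expect_length(res3$cover, 0)

  # identical runs are identical
  set.seed(91)
  b <- generate_benchmark(benchmark_spec(n = 100, c_min = 5, c_max = 20,
                                         on = 10, om = 2, seed = 17))
  r1 <- detect_communities(b$graph)
  r2 <- detect_communities(b$graph)
  expect_identical(unclass(r1$cover), unclass(r2$cover))
})

test_that("demonstration-style fixture yields overlapping nested covers", {
  g <- toy13_graph()
  res <- detect_communities(g, linkage = "al", min_size = 3, fill = FALSE)
  comp <- res$components[[1]]
  dend <- comp$dendrogram
  # some level exposes a genuinely overlapping cover
  found_overlap <- FALSE
  for (lev in 0:nrow(dend$merges)) {
    cov <- cover_at_level(dend, lev, min_size = 3, fill = FALSE, g = comp$graph)
    if (length(cov) >= 2 && any(membership_counts(cov) >= 2)) {
      found_overlap <- TRUE
      ov <- membership_counts(cov)
      expect_true(all(ov[ov >= 2] == 2))  # shared cut vertices sit in 2
      break
    }
  }
  expect_true(found_overlap)
  # pre-filter clusters are nested level to level
  lv <- ghac:::level_clusters(dend)
  for (l in seq_len(length(lv) - 1)) {
    for (cm in lv[[l]]) {
      expect_true(any(vapply(lv[[l + 1]], function(nx) all(cm %in% nx),
                             TRUE)))
    }
  }
})
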