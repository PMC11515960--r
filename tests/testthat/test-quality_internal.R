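test_that("Shen modularity reduces to Newman on partitions", {
  set.seed(101)
  for (i in 1:8) {
    g <- random_graph(sample(8:12, 1), 0.4)
    if (igraph::ecount(g) < 3) next
    memb <- sample(1:3, igraph::vcount(g), replace = TRUE)
    cover <- split(igraph::V(g)$name, memb)
    cover <- unname(cover[lengths(cover) > 0])
    expect_equal(shen_modularity(g, cover),
                 igraph::modularity(g, memb, weights = igraph::E(g)$weight),
                 tolerance = 1e-9)
  }
  # trivial partition scores zero
  g <- random_graph(8, 0.5)
  expect_equal(shen_modularity(g, list(igraph::V(g)$name)), 0,
               tolerance = 1e-12)
  # duplicating every community doubles O_v and scales each term by 1/4
  cover <- random_cover(g, 2)
  half <- shen_modularity(g, c(cover, cover))
  expect_equal(half, shen_modularity(g, cover) / 2, tolerance = 1e-12)
  expect_error(shen_modularity(g, list(c("nope"))), "not in graph")
})

test_that("Lazar modularity rewards cohesive communities", {
  # isolated clique community: maximal cohesion, term 1
  blocks <- rbind(t(utils::combn(paste0("a", 1:4), 2)),
                  t(utils::combn(paste0("b", 1:4), 2)))
  g <- gdf(blocks[, 1], blocks[, 2])
  cov <- list(paste0("a", 1:4), paste0("b", 1:4))
  expect_equal(lazar_modularity(g, cov), 1)
  # a community bleeding most weight outward scores negative
  star <- gdf(c("h", "h", "h", "x", "y", "z"),
              c("x", "y", "z", "y", "z", "x"))
  expect_lt(lazar_modularity(star, list(c("h", "x"))), 0)
  expect_warning(lazar_modularity(star, list(c("x", "y"), "h")), "size-1")
})

test_that("cut scores and transitivity follow the printed formulas", {
  g <- random_graph(8, 0.5)
  all_v <- list(igraph::V(g)$name)
  agg <- community_scores(g, all_v)$aggregate
  expect_equal(agg[["conductance"]], 0)
  expect_equal(agg[["expansion"]], 0)
  expect_equal(agg[["normalized_cut"]], 0)
  expect_equal(agg[["fodf"]], 0)

  # isolated unit triangle: internal density and transitivity are 1
  tri <- unit_triangle()
  agg2 <- community_scores(tri, list(c("a", "b", "c")))$aggregate
  expect_equal(agg2[["internal_density"]], 1)
  expect_equal(agg2[["internal_transitivity"]], 1)
})

test_that("internal metrics match brute-force oracles on random covers", {
  set.seed(111)
  for (i in 1:10) {
    g <- random_2ec_graph(sample(7:10, 1), 0.5)
    D <- wct_matrix(g)
    cover <- random_cover(g)
    cover <- cover[lengths(cover) >= 2]
    if (length(cover) < 2) next
    expect_equal(shen_modularity(g, cover), oracle_me(g, cover),
                 tolerance = 1e-9)
    expect_equal(suppressWarnings(lazar_modularity(g, cover)),
                 oracle_mov(g, cover), tolerance = 1e-9)
    agg <- community_scores(g, cover)$aggregate
    want <- oracle_cut_scores(g, cover)
    expect_equal(agg[names(want)], want, tolerance = 1e-9)
    expect_equal(dunn_index(g, cover, D, linkage = "al"),
                 oracle_dunn(g, cover, D, "al"), tolerance = 1e-9)
    expect_equal(as.numeric(silhouette_overlapping(cover, D)),
                 oracle_si(cover, D), tolerance = 1e-9)
  }
})

test_that("silhouette handles its degenerate conventions", {
  g <- gdf(c("a", "b", "a", "d", "e", "d", "c", "f"),
           c("b", "c", "c", "e", "f", "f", "d", "a"))
  D <- wct_matrix(g, use_weights = FALSE)
  si <- silhouette_overlapping(list(c("a", "b", "c"), c("d", "e", "f")), D)
  expect_gt(as.numeric(si), 0)
  expect_true(all(attr(si, "s") > 0))
  # every vertex in both identical communities: all s_i are 0
  labs <- igraph::V(g)$name
  si0 <- silhouette_overlapping(list(labs, labs), D)
  expect_equal(as.numeric(si0), 0)
  expect_true(all(attr(si0, "s") == 0))
  # fewer than two communities is undefined
  expect_true(is.na(silhouette_overlapping(list(labs), D)))
})

test_that("dunn index degenerates as specified", {
  g <- random_2ec_graph(8, 0.5)
  D <- wct_matrix(g)
  labs <- igraph::V(g)$name
  expect_true(is.na(dunn_index(g, list(labs), D)))
  # duplicated community: a zero-dissimilarity pair forces DI = 0
  cov <- list(labs[1:4], labs[1:4], labs[5:8])
  expect_equal(dunn_index(g, cov, D), 0)
})

test_that("the level sweep is consistent with detection", {
  set.seed(121)
  b <- generate_benchmark(benchmark_spec(n = 100, c_min = 5, c_max = 20,
                                         on = 10, om = 2, seed = 23))
  res <- detect_communities(b$graph, criterion = "silhouette")
  comp <- res$components[[1]]
  lv <- comp$levels
  expect_equal(lv$level, 0:(nrow(comp$dendrogram$merges)))
  ok <- !is.na(lv$silhouette)
  expect_true(any(ok))
  best <- lv[ok, ]
  best <- best[best$silhouette == max(best$silhouette), ]
  expect_equal(comp$best_level, best$level[1])
})
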