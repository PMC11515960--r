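# Graph fixtures and random generators used across the suite.  Everything is
# built in code; seeds are always set by the caller.

gdf <- function(from, to, weight = NULL) {
  df <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  if (!is.null(weight)) df$weight <- weight
  igraph::graph_from_data_frame(df, directed = FALSE)
}

unit_triangle <- function(w = c(1, 1, 1)) {
  gdf(c("a", "b", "a"), c("b", "c", "c"), w)
}

# Two triangles sharing the single vertex c (no bridge, one cut vertex).
bowtie_graph <- function() {
  gdf(c("a", "b", "a", "c", "d", "c"), c("b", "c", "c", "d", "e", "e"))
}

# Random G(n, p) with unit or random weights; optionally restricted to the
# largest 2-edge-connected component (so closed-trail distances are finite).
random_graph <- function(n, p = 0.45, weighted = TRUE, two_edge = FALSE) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  if (weighted)
    igraph::E(g)$weight <- round(stats::runif(igraph::ecount(g), 1, 5), 2)
  if (two_edge) {
    dec <- bridge_decomposition(g)
    if (length(dec$components) == 0L) return(NULL)
    g <- dec$components[[1L]]
  }
  g
}

# Random 2-edge-connected graph with >= 4 vertices (resamples until found).
random_2ec_graph <- function(n, p = 0.5, weighted = TRUE) {
  repeat {
    g <- random_graph(n, p, weighted, two_edge = TRUE)
    if (!is.null(g) && igraph::vcount(g) >= 4L) return(g)
  }
}

# Random overlapping cover over the vertices of g: k communities of random
# size >= 2, union covering all vertices.
random_cover <- function(g, k = sample(2:4, 1)) {
  labs <- igraph::V(g)$name
  n <- length(labs)
  cover <- lapply(seq_len(k), function(i)
    sort(sample(labs, sample(2:max(2, n - 1), 1))))
  missing <- setdiff(labs, unlist(cover))
  if (length(missing))
    cover[[1L]] <- sort(union(cover[[1L]], missing))
  cover
}

# 13-node demonstration-style fixture: a 6-clique block, a 4-clique block,
# and two triangles chained through shared vertices (every edge lies in a
# triangle, so the graph is 2-edge-connected with cut vertices).
toy13_graph <- function() {
  blockA <- t(utils::combn(paste0("a", 1:6), 2))     # 6-clique
  blockB <- t(utils::combn(paste0("b", 1:4), 2))     # 4-clique
  t1 <- rbind(c("a6", "b1"), c("a6", "x1"), c("b1", "x1"))  # bridge triangle
  t2 <- rbind(c("x1", "x2"), c("x1", "x3"), c("x2", "x3"))  # tail triangle
  el <- rbind(blockA, blockB, t1, t2)
  w <- rep(1, nrow(el))
  w[seq_len(nrow(blockA))] <- 2          # heavier core block
  gdf(el[, 1], el[, 2], w)
}
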