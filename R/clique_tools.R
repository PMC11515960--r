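# Maximal cliques as clustering base elements, and the clique-overlap weight
# w(Q) = |Q| + sum_{e in Q} w(e) / sum_{e in E} w(e): the integer part is the
# clique size, the fractional part breaks ties by heaviness.

#' Maximal cliques of a graph
#'
#' Enumerates all maximal cliques (Bron-Kerbosch with pivoting, via igraph) in
#' a deterministic order: decreasing size, then lexicographic on the sorted
#' member labels.  Isolated vertices belong to no clique.
#'
#' @param g Undirected graph.
#' @return List of character vectors of vertex names (each sorted).
#' @export
maximal_cliques <- function(g) {
  g <- ensure_names(g)
  cl <- igraph::max_cliques(g, min = 2)
  # vertices of degree >= 1 are covered by min = 2; a lone K1 component is not
  cl <- lapply(cl, function(x) sort(igraph::V(g)$name[as.integer(x)]))
  if (length(cl) == 0L) return(cl)
  key <- vapply(cl, paste, "", collapse = " ")
  cl[order(-vapply(cl, length, 1L), key)]
}

#' Clique weight
#'
#' `|Q|` plus the total weight of edges inside `Q` divided by the total weight
#' of all graph edges.  Size dominates (the fractional term is below 1 unless
#' the clique carries the entire graph weight); heaviness breaks ties.
#'
#' @param g Undirected weighted graph with at least one edge.
#' @param q Vertex set inducing a clique in `g`, `|q| >= 2`.
#' @return Positive real.
#' @export
clique_weight <- function(g, q) {
  g <- ensure_names(g)
  q <- as.character(q)
  if (length(q) < 2L) stop("clique must have at least 2 vertices")
  sg <- igraph::induced_subgraph(g, q)
  if (igraph::ecount(sg) != choose(length(q), 2))
    stop("q does not induce a clique")
  length(q) + sum(edge_weights(sg)) / sum(edge_weights(g))
}

#' Weight of the densest clique in an overlap
#'
#' Maximum clique weight over the maximal cliques of the subgraph induced on
#' `overlap`; 0 when the overlap is empty or induces no edge.  This is the
#' denominator term of the GHAC dissimilarities: for disjoint clusters it is 0
#' and plain linkage is recovered.
#'
#' @param g Undirected weighted graph.
#' @param overlap Vertex set (possibly empty).
#' @return Nonnegative real.
#' @export
max_overlap_clique_weight <- function(g, overlap) {
  g <- ensure_names(g)
  overlap <- as.character(overlap)
  if (length(overlap) < 2L) return(0)
  labs <- igraph::V(g)$name
  idx <- match(overlap, labs)
  if (anyNA(idx)) stop("overlap contains vertices not in g")
  W <- weighted_adjacency(g)
  .max_overlap_clique_weight_cpp(W, as.integer(idx - 1L),
                                 sum(edge_weights(g)))
}

#' Write cliques to a text file, one per line
#'
#' @param cliques List of character vectors.
#' @param path Output path.
#' @export
write_cliques <- function(cliques, path) {
  writeLines(vapply(cliques, paste, "", collapse = " "), path)
  invisible(path)
}
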