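# Closed-trail distances.  The minimal closed trail through u and v equals a
# minimum-cost pair of edge-disjoint u-v paths (the trail splits into two
# edge-disjoint u-v trails; with positive costs the optimum is attained by
# simple paths), so distances are computed with Suurballe's algorithm:
# shortest-path tree, reduced costs, residual reversal.

ensure_names <- function(g) {
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}

edge_costs <- function(g, use_weights) {
  if (use_weights) 1 / edge_weights(g) else rep(1, igraph::ecount(g))
}

#' Minimum-cost pair of edge-disjoint paths (Suurballe)
#'
#' Finds two edge-disjoint paths between `s` and `t` with minimal total cost.
#' Paths may share vertices (trails through cut vertices are allowed) but no
#' edge.  When fewer than two edge-disjoint paths exist (`s` and `t`
#' separated by a bridge) the result is infeasible with cost `Inf`.
#'
#' @param g Undirected graph.
#' @param s,t Distinct vertex names (or indices).
#' @param edge_cost Positive cost per edge, aligned with `igraph::E(g)`;
#'   defaults to unit costs.
#' @return List with `cost`, `feasible`, and (when feasible) `paths`, a list
#'   of two character vectors of vertex names.
#' @export
suurballe_pair <- function(g, s, t, edge_cost = NULL) {
  g <- ensure_names(g)
  labs <- igraph::V(g)$name
  si <- match(as.character(s), labs); ti <- match(as.character(t), labs)
  if (is.na(si) || is.na(ti)) stop("s and t must be vertices of g")
  if (si == ti) stop("s and t must be distinct")
  if (is.null(edge_cost)) edge_cost <- rep(1, igraph::ecount(g))
  if (any(edge_cost <= 0)) stop("edge costs must be positive")
  el <- igraph::as_edgelist(g, names = FALSE)
  res <- .suurballe_pair_cpp(igraph::vcount(g),
                             as.integer(el[, 1] - 1L), as.integer(el[, 2] - 1L),
                             as.numeric(edge_cost),
                             as.integer(si - 1L), as.integer(ti - 1L))
  if (isTRUE(res$feasible))
    res$paths <- lapply(res$paths, function(p) labs[p + 1L])
  res
}

#' Weighted closed-trail distance between two vertices
#'
#' The minimum, over closed trails containing both `u` and `v`, of the trail
#' length (unweighted mode) or of the sum of reciprocal edge weights
#' (weighted mode).  `Inf` when no closed trail through both exists.
#'
#' @param g Undirected weighted graph.
#' @param u,v Distinct vertices.
#' @param use_weights If `TRUE` (default) each edge costs `1/w(e)`, otherwise
#'   1.
#' @return Nonnegative real, possibly `Inf`.
#' @export
wct_distance <- function(g, u, v, use_weights = TRUE) {
  suurballe_pair(g, u, v, edge_cost = edge_costs(g, use_weights))$cost
}

#' Closed-trail distance matrix
#'
#' All pairwise weighted closed-trail distances, with a zero diagonal by
#' convention so the matrix feeds standard clustering formulas.
#'
#' @inheritParams wct_distance
#' @return Symmetric numeric matrix with vertex names as dimnames.
#' @export
wct_matrix <- function(g, use_weights = TRUE) {
  g <- ensure_names(g)
  n <- igraph::vcount(g)
  if (n == 0L) stop("graph is empty")
  labs <- igraph::V(g)$name
  if (igraph::ecount(g) == 0L) {
    D <- matrix(Inf, n, n, dimnames = list(labs, labs)); diag(D) <- 0
    return(D)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  D <- .wct_matrix_cpp(n, as.integer(el[, 1] - 1L), as.integer(el[, 2] - 1L),
                       edge_costs(g, use_weights))
  dimnames(D) <- list(labs, labs)
  D
}

#' Write a distance matrix as TSV
#'
#' @param d Matrix with dimnames.
#' @param path Output path.
#' @export
write_distance_matrix <- function(d, path) {
  write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}
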