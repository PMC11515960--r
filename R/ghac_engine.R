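# The GHAC engine: agglomerative clustering over maximal-clique base
# elements.  The dissimilarity between clusters Ci, Cj is the complete- or
# average-linkage aggregate of closed-trail distances between exclusive
# members, divided by 1 + the weight of the densest clique in the overlap.
# Nested clusters (an empty exclusive side) have dissimilarity 0 and are
# absorbed immediately.

linkage_code <- function(linkage) {
  linkage <- match.arg(tolower(linkage), c("al", "cl"))
  if (linkage == "cl") 0L else 1L
}

# Internal shared-state helper: aligned D/W matrices for a graph.
engine_matrices <- function(g, dist = NULL, use_weights = TRUE) {
  g <- ensure_names(g)
  if (is.null(dist)) dist <- wct_matrix(g, use_weights = use_weights)
  labs <- igraph::V(g)$name
  if (!identical(rownames(dist), labs))
    dist <- dist[labs, labs, drop = FALSE]
  W <- weighted_adjacency(g)
  list(g = g, D = dist, W = W, labs = labs, wtotal = sum(edge_weights(g)))
}

#' Cluster dissimilarities (complete and average linkage)
#'
#' The complete-linkage dissimilarity is the maximum closed-trail distance
#' between exclusive members of the two clusters; the average-linkage variant
#' sums those distances and divides by the size of the symmetric difference
#' of the clusters (set `al_denominator = "pairs"` for the conventional
#' pair-count average).  Both are divided by `1 +` the weight of the densest
#' clique in the overlap, and both are 0 when one cluster contains the other.
#'
#' @param g Undirected weighted graph.
#' @param dist Closed-trail distance matrix over the vertices of `g` (from
#'   [wct_matrix()]).
#' @param a,b Character vectors of vertex names (the two clusters).
#' @param al_denominator `"symdiff"` (default) or `"pairs"`.
#' @return Nonnegative real.
#' @export
dissimilarity_cl <- function(g, dist, a, b) {
  .dissimilarity(g, dist, a, b, 0L, FALSE)
}

#' @rdname dissimilarity_cl
#' @export
dissimilarity_al <- function(g, dist, a, b,
                             al_denominator = c("symdiff", "pairs")) {
  al_denominator <- match.arg(al_denominator)
  .dissimilarity(g, dist, a, b, 1L, al_denominator == "pairs")
}

.dissimilarity <- function(g, dist, a, b, code, paircount) {
  em <- engine_matrices(g, dist)
  ai <- match(as.character(a), em$labs); bi <- match(as.character(b), em$labs)
  if (anyNA(ai) || anyNA(bi)) stop("cluster vertices must be in g")
  .dissimilarity_cpp(em$D, em$W, as.integer(ai - 1L), as.integer(bi - 1L),
                     code, em$wtotal, paircount)
}

#' Agglomerate maximal cliques into a dendrogram
#'
#' Greedy agglomerative clustering: at each step the pair of clusters with
#' globally minimal dissimilarity is merged (ties break on the lowest pair of
#' cluster ids).  All dissimilarities involving the merged cluster are
#' recomputed from the cluster vertex sets; the overlap term rules out
#' Lance-Williams updates.  Recorded heights are raw and need not be
#' monotone: a growing overlap can shrink dissimilarity.
#'
#' @param g Undirected weighted graph, typically one 2-edge-connected
#'   component.
#' @param dist Closed-trail distance matrix (computed if `NULL`).
#' @param cliques Base cliques (computed via [maximal_cliques()] if `NULL`).
#' @param linkage `"al"` (average, default) or `"cl"` (complete).
#' @param al_denominator See [dissimilarity_al()].
#' @param use_weights Passed to [wct_matrix()] when `dist` is `NULL`.
#' @return Object of class `ghac_dendrogram`: list with `merges` (data frame
#'   `level`, `left`, `right`, `height`, `new`, ids 1-based over base cliques
#'   then merged clusters), `base` (the clique list), `labels`, `linkage`.
#' @export
agglomerate <- function(g, dist = NULL, cliques = NULL,
                        linkage = c("al", "cl"),
                        al_denominator = c("symdiff", "pairs"),
                        use_weights = TRUE) {
  linkage <- match.arg(linkage)
  al_denominator <- match.arg(al_denominator)
  em <- engine_matrices(g, dist, use_weights)
  if (is.null(cliques)) cliques <- maximal_cliques(em$g)
  if (length(cliques) == 0L) stop("graph has no cliques of size >= 2")
  cl_idx <- lapply(cliques, function(q) as.integer(match(q, em$labs) - 1L))
  res <- .agglomerate_cpp(em$D, em$W, cl_idx, linkage_code(linkage),
                          em$wtotal, al_denominator == "pairs")
  merges <- data.frame(level = seq_along(res$left),
                       left = res$left + 1L, right = res$right + 1L,
                       height = res$height, new = res$newid + 1L)
  structure(list(merges = merges, base = cliques, labels = em$labs,
                 linkage = linkage, al_denominator = al_denominator),
            class = "ghac_dendrogram")
}

#' @export
print.ghac_dendrogram <- function(x, ...) {
  cat("GHAC dendrogram (", x$linkage, " linkage): ", length(x$base),
      " base cliques, ", nrow(x$merges), " merges over ",
      length(x$labels), " vertices\n", sep = "")
  invisible(x)
}

# Active cluster vertex sets at every level.  Element [[l + 1]] is the list
# of clusters after l merges, named by cluster id.
level_clusters <- function(dend) {
  K <- length(dend$base)
  clusters <- dend$base
  names(clusters) <- as.character(seq_len(K))
  out <- vector("list", nrow(dend$merges) + 1L)
  out[[1L]] <- clusters
  for (l in seq_len(nrow(dend$merges))) {
    m <- dend$merges[l, ]
    merged <- sort(union(clusters[[as.character(m$left)]],
                         clusters[[as.character(m$right)]]))
    clusters[[as.character(m$left)]] <- NULL
    clusters[[as.character(m$right)]] <- NULL
    clusters[[as.character(m$new)]] <- merged
    out[[l + 1L]] <- clusters
  }
  out
}

# Post-processing shared by cover_at_level and the level sweep.  `W` lets
# sweeps reuse one weighted adjacency across levels.
postprocess_cover <- function(clusters, min_size, fill, g, W = NULL) {
  comm <- clusters[!duplicated(lapply(clusters, identity))]
  comm <- comm[vapply(comm, length, 1L) >= min_size]
  if (length(comm) == 0L)
    return(structure(list(), class = "ghac_cover", uncovered = character(0)))
  if (fill) comm <- fill_cover(comm, g, W)
  covered <- unique(unlist(comm))
  unc <- setdiff(igraph::V(g)$name, covered)
  structure(comm, class = "ghac_cover", uncovered = unc)
}

# One synchronous pass: each uncovered vertex joins the community most
# frequent among its neighbours (pre-fill assignments only); ties go to the
# community with the larger total edge weight from the vertex, then to the
# lowest community id.  Vertices with no covered neighbour stay uncovered.
fill_cover <- function(comm, g, W = NULL) {
  covered <- unique(unlist(comm))
  labs <- igraph::V(g)$name
  unc <- sort(setdiff(labs, covered))
  if (length(unc) == 0L) return(comm)
  if (is.null(W)) W <- weighted_adjacency(g)
  member <- lapply(comm, function(cm) labs %in% cm)
  add <- vector("list", length(comm))
  for (v in unc) {
    vi <- match(v, labs)
    nb <- W[vi, ] > 0
    freq <- vapply(member, function(m) sum(nb & m), 1L)
    if (all(freq == 0L)) next
    best <- which(freq == max(freq))
    if (length(best) > 1L) {
      wsum <- vapply(best, function(k) sum(W[vi, nb & member[[k]]]), 1)
      best <- best[wsum == max(wsum)]
    }
    k <- min(best)
    add[[k]] <- c(add[[k]], v)
  }
  for (k in seq_along(comm))
    if (length(add[[k]])) comm[[k]] <- sort(c(comm[[k]], add[[k]]))
  comm
}

#' Extract the network cover at a dendrogram level
#'
#' Materialises the active clusters after `level` merges as vertex sets,
#' removes duplicates and communities smaller than `min_size`, and (when
#' `fill` is on) attaches uncovered vertices to the community most frequent
#' among their neighbours.
#'
#' @param dend A [agglomerate()] dendrogram.
#' @param level Integer in `0..nrow(dend$merges)`.
#' @param min_size Minimum community size kept (default 5).
#' @param fill Run the neighbour-fill step (default `TRUE`).
#' @param g The graph the dendrogram was built on (for the fill step and the
#'   uncovered-vertex bookkeeping).
#' @return Object of class `ghac_cover`: a list of character vectors, with
#'   attribute `uncovered`.
#' @export
cover_at_level <- function(dend, level, min_size = 5, fill = TRUE, g) {
  if (level < 0 || level > nrow(dend$merges))
    stop("level must be in 0..", nrow(dend$merges))
  g <- ensure_names(g)
  clusters <- level_clusters(dend)[[level + 1L]]
  postprocess_cover(clusters, min_size, fill, g)
}

#' Membership counts of a cover
#'
#' @param cover List of character vectors.
#' @return Named integer vector `O_v` over covered vertices.
#' @export
membership_counts <- function(cover) {
  if (length(cover) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(unlist(lapply(cover, unique)))
  setNames(as.integer(tab), names(tab))
}

criterion_directions <- c(me = 1, mov = 1, silhouette = 1, dunn = 1,
                          internal_density = 1, internal_transitivity = 1,
                          conductance = -1, expansion = -1, ratio_cut = -1,
                          normalized_cut = -1, fodf = -1)

#' Detect overlapping communities (end-to-end GHAC)
#'
#' Runs the full pipeline: optional weight rescaling to `[1, s]`, bridge
#' decomposition, and per 2-edge-connected component the closed-trail
#' distance matrix, maximal cliques, agglomeration, and a sweep over
#' dendrogram levels scoring each post-processed cover with the chosen
#' internal criterion.  The returned cover is taken at the level optimising
#' the criterion (ties: fewest communities, then lowest level); component
#' covers are combined and, when `fill` is on, a final whole-graph fill
#' attaches bridge and residual vertices.
#'
#' @param g Undirected weighted graph.
#' @param linkage `"al"` or `"cl"`.
#' @param min_size Minimum community size (default 5).
#' @param criterion Internal criterion driving the cut; one of
#'   `r paste0('"', names(criterion_directions), '"', collapse = ", ")`.
#' @param fill Attach uncovered vertices to neighbouring communities.
#' @param normalize Rescale weights with [normalize_weights()] first.
#' @param s Upper end of the weight interval used when normalising.
#' @param use_weights Use `1/w` edge costs for distances (default) or unit
#'   costs.
#' @param al_denominator See [dissimilarity_al()].
#' @return Object of class `ghac_result`: list with `cover`, `components`
#'   (per-component list carrying `dendrogram`, `levels` table, `best_level`,
#'   `dist`), `criterion`, `graph`.  When no component of size `>= 3` exists
#'   the cover is empty.
#' @export
detect_communities <- function(g, linkage = c("al", "cl"), min_size = 5,
                               criterion = "silhouette", fill = TRUE,
                               normalize = TRUE, s = 10, use_weights = TRUE,
                               al_denominator = c("symdiff", "pairs")) {
  linkage <- match.arg(linkage)
  al_denominator <- match.arg(al_denominator)
  criterion <- match.arg(criterion, names(criterion_directions))
  g <- ensure_names(g)
  if (normalize && igraph::ecount(g) > 0L) g <- normalize_weights(g, s)
  dec <- bridge_decomposition(g)
  comps <- dec$components[vapply(dec$components, igraph::vcount, numeric(1)) >= 3L]
  out <- list(cover = structure(list(), class = "ghac_cover",
                                uncovered = igraph::V(g)$name),
              components = list(), criterion = criterion, graph = g,
              decomposition = dec)
  class(out) <- "ghac_result"
  if (length(comps) == 0L) return(out)

  cover <- list()
  for (ci in seq_along(comps)) {
    gc <- comps[[ci]]
    D <- wct_matrix(gc, use_weights = use_weights)
    dend <- agglomerate(gc, dist = D, linkage = linkage,
                        al_denominator = al_denominator)
    lv <- evaluate_levels(dend, gc, D, metrics = criterion,
                          min_size = min_size, fill = fill)
    sel <- select_level(lv, criterion)
    cov <- cover_at_level(dend, sel, min_size = min_size, fill = fill, g = gc)
    cover <- c(cover, unclass(cov))
    out$components[[ci]] <- list(graph = gc, dendrogram = dend, dist = D,
                                 levels = lv, best_level = sel)
  }
  if (length(cover) && fill) cover <- fill_cover(cover, g)
  covered <- unique(unlist(cover))
  out$cover <- structure(cover, class = "ghac_cover",
                         uncovered = setdiff(igraph::V(g)$name, covered))
  out
}

# Argmax/argmin of the criterion over valid levels; ties resolved by fewer
# communities, then lower level.  If no level has a defined criterion value,
# fall back to the level with the fewest (nonzero) communities, then lowest.
select_level <- function(levels_table, criterion) {
  dir <- criterion_directions[[criterion]]
  val <- levels_table[[criterion]] * dir
  ok <- !is.na(val)
  if (any(ok)) {
    cand <- levels_table[ok, ]
    cand_val <- val[ok]
    best <- cand_val == max(cand_val)
    cand <- cand[best, ]
    cand <- cand[cand$n_communities == min(cand$n_communities), ]
    return(cand$level[1L])
  }
  nz <- levels_table[levels_table$n_communities > 0L, ]
  if (nrow(nz) == 0L) return(levels_table$level[nrow(levels_table)])
  nz <- nz[nz$n_communities == min(nz$n_communities), ]
  nz$level[1L]
}

#' @export
print.ghac_result <- function(x, ...) {
  cat("GHAC result: ", length(x$cover), " communities, criterion = ",
      x$criterion, "\n", sep = "")
  ov <- membership_counts(x$cover)
  cat("  overlapping vertices (O_v >= 2): ", sum(ov >= 2), "\n", sep = "")
  if (length(attr(x$cover, "uncovered")))
    cat("  uncovered vertices: ", length(attr(x$cover, "uncovered")), "\n",
        sep = "")
  invisible(x)
}

#' Dendrogram merges as JSON
#'
#' @param dend A `ghac_dendrogram`.
#' @param path Output path.
#' @export
write_dendrogram_json <- function(dend, path) {
  jsonlite::write_json(list(linkage = dend$linkage,
                            n_base_cliques = length(dend$base),
                            base = lapply(dend$base, identity),
                            merges = dend$merges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
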