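# Internal (ground-truth-free) quality criteria for overlapping covers.
# Per-community scores are aggregated by averaging over communities; Shen's
# and Lazar's modularities, the Dunn index and the Silhouette index are
# direct cover-level values.

cover_membership <- function(cover, labs) {
  O <- setNames(integer(length(labs)), labs)
  for (cm in cover) O[cm] <- O[cm] + 1L
  O
}

check_cover_in_graph <- function(cover, labs) {
  miss <- setdiff(unique(unlist(cover)), labs)
  if (length(miss)) stop("cover contains vertices not in graph: ",
                         paste(head(miss, 5), collapse = ", "))
}

#' Shen's overlap-aware modularity
#'
#' Extends Newman's weighted modularity to covers by down-weighting each
#' vertex pair by the product of their membership counts:
#' `Me = 1/(2m) sum_k sum_{i,j in Ck} (1/(Oi Oj)) (w_ij - wdeg(i) wdeg(j)/(2m))`,
#' where `2m` is the total weighted degree.  For a partition it equals
#' Newman's weighted modularity.
#'
#' @param g Undirected weighted graph.
#' @param cover List of character vectors (communities).
#' @param W Optional precomputed weighted adjacency matrix of `g`.
#' @return Real number.
#' @export
shen_modularity <- function(g, cover, W = NULL) {
  g <- ensure_names(g)
  labs <- igraph::V(g)$name
  check_cover_in_graph(cover, labs)
  if (length(cover) == 0L) stop("cover is empty")
  if (is.null(W)) W <- weighted_adjacency(g)
  wdeg <- rowSums(W)
  tw2 <- sum(wdeg)
  if (tw2 == 0) return(0)
  O <- cover_membership(cover, labs)
  acc <- 0
  for (cm in cover) {
    idx <- match(unique(cm), labs)
    u <- 1 / O[idx]
    acc <- acc + drop(crossprod(u, W[idx, idx, drop = FALSE] %*% u)) -
      sum(u * wdeg[idx])^2 / tw2
  }
  acc / tw2
}

#' Lazar's overlap-aware modularity
#'
#' Each community scores the mean, over members, of (internal weight minus
#' external weight) divided by the member's weighted degree times its
#' membership count, multiplied by the community's internal edge density;
#' `Mov` is the mean over communities.  Size-1 communities are excluded with
#' a warning (the density term is undefined).
#'
#' @inheritParams shen_modularity
#' @return Real number.
#' @export
lazar_modularity <- function(g, cover, W = NULL) {
  g <- ensure_names(g)
  labs <- igraph::V(g)$name
  check_cover_in_graph(cover, labs)
  if (is.null(W)) W <- weighted_adjacency(g)
  A <- (W > 0) + 0
  wdeg <- rowSums(W)
  O <- cover_membership(cover, labs)
  sizes <- vapply(cover, function(cm) length(unique(cm)), 1L)
  if (any(sizes < 2L)) {
    warning("excluding ", sum(sizes < 2L), " size-1 communit(y/ies) from Mov")
    cover <- cover[sizes >= 2L]
  }
  if (length(cover) == 0L) stop("no community of size >= 2")
  terms <- vapply(cover, function(cm) {
    idx <- match(unique(cm), labs)
    nk <- length(idx)
    win <- rowSums(W[idx, idx, drop = FALSE])
    wout <- wdeg[idx] - win
    denom <- wdeg[idx] * O[idx]
    contrib <- ifelse(denom > 0, (win - wout) / denom, 0)
    ne <- sum(A[idx, idx]) / 2
    sum(contrib) * ne / (nk * choose(nk, 2))
  }, 1)
  mean(terms)
}

#' Per-community cut and density scores
#'
#' Evaluates, for every community `C` with `wcut(C)` the weight crossing the
#' boundary and `wvol(C)` the total weighted degree of members: conductance
#' `wcut/wvol`, expansion `wcut/n_i`, internal density
#' `(wvol - wcut)/(n_i (n_i - 1))`, ratio cut `wcut/(n_i (n - n_i))`,
#' normalized cut `wcut/wvol + wcut/wvol(V \\ C)`, Flake ODF (fraction of
#' members with at most half their weight inside), and internal transitivity
#' (mean clustering over internal neighbourhoods, unweighted).  Undefined
#' values (e.g. conductance of a zero-volume community) are `NA` and excluded
#' from the aggregate means.
#'
#' @inheritParams shen_modularity
#' @return List with `per_community` (data frame, one row per community) and
#'   `aggregate` (named numeric vector of means over communities).
#' @export
community_scores <- function(g, cover, W = NULL) {
  g <- ensure_names(g)
  labs <- igraph::V(g)$name
  check_cover_in_graph(cover, labs)
  if (is.null(W)) W <- weighted_adjacency(g)
  A <- (W > 0) + 0
  wdeg <- rowSums(W)
  n <- length(labs)
  tw2 <- sum(wdeg)
  rows <- lapply(seq_along(cover), function(k) {
    idx <- match(unique(cover[[k]]), labs)
    ni <- length(idx)
    win <- rowSums(W[idx, idx, drop = FALSE])
    wvol <- sum(wdeg[idx])
    wcut <- wvol - sum(win)
    volc <- tw2 - wvol
    cond <- if (wcut == 0) 0 else if (wvol > 0) wcut / wvol else NA_real_
    nc <- if (wcut == 0) 0 else if (wvol > 0 && volc > 0)
      wcut / wvol + wcut / volc else NA_real_
    ind <- if (ni >= 2) (wvol - wcut) / (ni * (ni - 1)) else NA_real_
    rc <- if (wcut == 0) 0 else if (ni < n) wcut / (ni * (n - ni)) else NA_real_
    fodf <- mean(win <= wdeg[idx] / 2)
    int <- mean(vapply(idx, function(i) {
      S <- idx[A[i, idx] > 0 & idx != i]
      kint <- length(S)
      if (kint < 2) return(0)
      sum(A[S, S]) / (kint * (kint - 1))
    }, 1))
    data.frame(community = k, n = ni, conductance = cond,
               expansion = wcut / ni, internal_density = ind,
               ratio_cut = rc, normalized_cut = nc, fodf = fodf,
               internal_transitivity = int)
  })
  per <- do.call(rbind, rows)
  agg <- colMeans(per[, -(1:2), drop = FALSE], na.rm = TRUE)
  agg[is.nan(agg)] <- NA_real_
  list(per_community = per, aggregate = agg)
}

#' Dunn index of a cover
#'
#' Ratio of the smallest between-community dissimilarity (the same GHAC
#' linkage dissimilarity used for clustering) to the largest community
#' diameter under the closed-trail distance.  Needs at least two
#' communities; singleton communities are excluded from the diameter.
#'
#' @inheritParams shen_modularity
#' @param dist Closed-trail distance matrix over the vertices of `g`.
#' @param linkage,al_denominator Dissimilarity variant, as in
#'   [agglomerate()].
#' @param em Internal: precomputed matrices from an engine sweep.
#' @return Real number, or `NA` when undefined.
#' @export
dunn_index <- function(g, cover, dist, linkage = c("al", "cl"),
                       al_denominator = c("symdiff", "pairs"), em = NULL) {
  linkage <- match.arg(linkage)
  al_denominator <- match.arg(al_denominator)
  if (length(cover) < 2L) return(NA_real_)
  if (is.null(em)) em <- engine_matrices(g, dist)
  idxs <- lapply(cover, function(cm) match(unique(cm), em$labs))
  diams <- vapply(idxs, function(ix) {
    if (length(ix) < 2L) return(NA_real_)
    max(em$D[ix, ix])
  }, 1)
  if (all(is.na(diams))) return(NA_real_)
  dmax <- max(diams, na.rm = TRUE)
  if (dmax <= 0) return(NA_real_)
  code <- linkage_code(linkage)
  pc <- al_denominator == "pairs"
  dmin <- Inf
  for (i in seq_along(idxs)[-length(idxs)])
    for (j in (i + 1):length(idxs)) {
      d <- .dissimilarity_cpp(em$D, em$W, as.integer(idxs[[i]] - 1L),
                              as.integer(idxs[[j]] - 1L), code, em$wtotal, pc)
      if (d < dmin) dmin <- d
    }
  dmin / dmax
}

#' Overlap-adjusted Silhouette index
#'
#' Classical silhouette generalised to covers: for vertex `i` with membership
#' set `P`, `a_ip` is the mean closed-trail distance to the other members of
#' community `p` (sum over members, including the zero self term, divided by
#' `|Cp| - 1`), `b_i` the smallest mean distance to any community not
#' containing `i`, and `s_i` the average of `(b_i - a_ip)/max(a_ip, b_i)`
#' over `P`.  Memberships in singleton communities are skipped; a vertex
#' belonging to every community gets `s_i = 0` by convention.  The index is
#' the mean of `s_i` over covered vertices.
#'
#' @param cover List of character vectors.
#' @param dist Closed-trail distance matrix covering all cover vertices.
#' @return The index value, with per-vertex scores in attribute `s`.
#' @export
silhouette_overlapping <- function(cover, dist) {
  if (length(cover) < 2L) return(NA_real_)
  labs <- rownames(dist)
  check_cover_in_graph(cover, labs)
  covered <- sort(unique(unlist(cover)))
  cmat <- vapply(cover, function(cm) labs %in% cm, logical(length(labs)))
  sizes <- colSums(cmat)
  sums <- dist %*% cmat                   # sums[i, k] = sum_{j in Ck} d(i, j)
  s <- setNames(numeric(length(covered)), covered)
  for (v in covered) {
    vi <- match(v, labs)
    inP <- cmat[vi, ]
    means_out <- sums[vi, !inP] / sizes[!inP]
    b <- if (any(!inP)) min(means_out) else NA_real_
    ps <- which(inP & sizes >= 2)
    if (is.na(b) || length(ps) == 0L) { s[v] <- 0; next }
    a <- sums[vi, ps] / (sizes[ps] - 1)
    s[v] <- mean((b - a) / pmax(a, b))
  }
  structure(mean(s), s = s)
}

#' Score every dendrogram level
#'
#' Sweeps the dendrogram, post-processes the cover at each level (duplicate
#' removal, size filter, optional fill) and scores it on the requested
#' internal metrics.  Covers with fewer than two communities are marked
#' missing.
#'
#' @param dend A [agglomerate()] dendrogram.
#' @param g The component graph.
#' @param dist Closed-trail distance matrix of `g`.
#' @param metrics Character vector of metric names (see
#'   `names(ghac:::criterion_directions)`); defaults to all.
#' @param min_size,fill Passed to the cover post-processing.
#' @param levels Optional integer vector restricting which levels are scored
#'   (community counts are still reported for every level).
#' @return Data frame with `level`, `n_communities`, and one column per
#'   metric.
#' @export
evaluate_levels <- function(dend, g, dist,
                            metrics = names(criterion_directions),
                            min_size = 5, fill = TRUE, levels = NULL) {
  metrics <- match.arg(metrics, names(criterion_directions),
                       several.ok = TRUE)
  g <- ensure_names(g)
  em <- engine_matrices(g, dist)
  lvls <- level_clusters(dend)
  out <- vector("list", length(lvls))
  for (l in seq_along(lvls)) {
    cov <- postprocess_cover(lvls[[l]], min_size, fill, g, em$W)
    row <- list(level = l - 1L, n_communities = length(cov))
    vals <- setNames(rep(NA_real_, length(metrics)), metrics)
    if (length(cov) >= 2L && (is.null(levels) || (l - 1L) %in% levels))
      vals[] <- score_cover_internal(g, cov, em, metrics,
                                     linkage = dend$linkage,
                                     al_denominator = dend$al_denominator)
    out[[l]] <- c(row, as.list(vals))
  }
  do.call(rbind, lapply(out, as.data.frame))
}

# Scores one post-processed cover on the requested internal metrics.
score_cover_internal <- function(g, cov, em, metrics, linkage,
                                 al_denominator) {
  cut_metrics <- intersect(metrics, c("conductance", "expansion",
                                      "internal_density", "ratio_cut",
                                      "normalized_cut", "fodf",
                                      "internal_transitivity"))
  vals <- setNames(rep(NA_real_, length(metrics)), metrics)
  if ("me" %in% metrics) vals["me"] <- shen_modularity(g, cov, em$W)
  if ("mov" %in% metrics)
    vals["mov"] <- suppressWarnings(lazar_modularity(g, cov, em$W))
  if (length(cut_metrics)) {
    agg <- community_scores(g, cov, em$W)$aggregate
    vals[cut_metrics] <- agg[cut_metrics]
  }
  if ("dunn" %in% metrics)
    vals["dunn"] <- dunn_index(g, cov, em$D, linkage = linkage,
                               al_denominator = al_denominator, em = em)
  if ("silhouette" %in% metrics)
    vals["silhouette"] <- as.numeric(silhouette_overlapping(cov, em$D))
  vals
}

#' Plot internal metrics across dendrogram levels
#'
#' Simple metric-vs-level line chart (requires ggplot2).
#'
#' @param levels_table Output of [evaluate_levels()].
#' @param metrics Metrics to show; defaults to all present.
#' @return A ggplot object.
#' @export
plot_level_metrics <- function(levels_table, metrics = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  cols <- setdiff(names(levels_table), c("level", "n_communities"))
  if (!is.null(metrics)) cols <- intersect(cols, metrics)
  long <- do.call(rbind, lapply(cols, function(m)
    data.frame(level = levels_table$level, metric = m,
               value = levels_table[[m]])))
  ggplot2::ggplot(long, ggplot2::aes(x = level, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "dendrogram level", y = NULL)
}
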