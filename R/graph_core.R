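#' Read a weighted edge list
#'
#' Parses a delimited edge-list file with columns `u`, `v` and an optional
#' positive weight (default 1).  Lines starting with `#` and blank lines are
#' skipped.  Self-loop rows are dropped with a warning; duplicate rows for the
#' same unordered pair keep the first occurrence and warn.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field delimiter; defaults to tab.  Any run of the
#'   delimiter and surrounding whitespace separates fields.
#' @return An undirected simple [igraph::igraph] graph with a positive
#'   `weight` edge attribute.  An empty file yields an empty graph.
#' @export
read_edge_list <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  u <- character(0); v <- character(0); w <- numeric(0)
  for (i in idx) {
    f <- strsplit(trimws(lines[i]), delimiter, fixed = TRUE)[[1]]
    f <- f[nzchar(trimws(f))]
    if (length(f) < 2L) stop("line ", i, ": expected at least 2 fields")
    wi <- 1
    if (length(f) >= 3L) {
      wi <- suppressWarnings(as.numeric(f[3]))
      if (is.na(wi)) stop("line ", i, ": non-numeric weight '", f[3], "'")
      if (wi <= 0) stop("line ", i, ": nonpositive weight ", wi)
    }
    u <- c(u, trimws(f[1])); v <- c(v, trimws(f[2])); w <- c(w, wi)
  }
  loops <- u == v
  if (any(loops)) {
    warning(sum(loops), " self-loop row(s) dropped")
    u <- u[!loops]; v <- v[!loops]; w <- w[!loops]
  }
  key <- ifelse(u < v, paste(u, v), paste(v, u))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge row(s) dropped (first occurrence kept)")
    u <- u[!dup]; v <- v[!dup]; w <- w[!dup]
  }
  if (length(u) == 0L) return(igraph::make_empty_graph(0, directed = FALSE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = u, to = v, weight = w, stringsAsFactors = FALSE),
    directed = FALSE)
  g
}

#' Write a weighted edge list
#'
#' @param g Undirected weighted graph.
#' @param path Output file path.
#' @param delimiter Field delimiter.
#' @export
write_edge_list <- function(g, path, delimiter = "\t") {
  el <- igraph::as_edgelist(g)
  w <- edge_weights(g)
  df <- data.frame(el[, 1], el[, 2], w)
  write.table(df, path, sep = delimiter, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write covers
#'
#' A cover file holds one community per line, node labels whitespace
#' separated.  [write_cover()] orders communities by decreasing size, then by
#' the lexicographically smallest member, with members sorted, so output is
#' deterministic and `read_cover(write_cover(x))` reproduces `x` up to that
#' canonical ordering.
#'
#' @param cover A list of character vectors of node labels.
#' @param path File path.
#' @return `read_cover` returns a list of character vectors.
#' @export
read_cover <- function(path) {
  if (!file.exists(path)) stop("cover file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
}

#' @rdname read_cover
#' @export
write_cover <- function(cover, path) {
  if (length(cover) == 0L) stop("cover is empty")
  cover <- lapply(cover, function(x) sort(as.character(x)))
  ord <- order(-vapply(cover, length, 1L),
               vapply(cover, function(x) x[1], ""))
  writeLines(vapply(cover[ord], paste, "", collapse = " "), path)
  invisible(path)
}

#' GraphML interchange
#'
#' Thin wrappers around [igraph::read_graph()] / [igraph::write_graph()]
#' keeping the `weight` edge attribute.
#'
#' @param path File path.
#' @param g Graph to write.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  g <- igraph::as_undirected(g, mode = "collapse")
  g
}

#' @rdname read_graphml
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# Edge weights with a unit fallback so unweighted graphs behave as all-ones.
edge_weights <- function(g) {
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  if (any(w <= 0)) stop("all edge weights must be positive")
  w
}

# Weighted adjacency as a dense base matrix with vertex names.
weighted_adjacency <- function(g) {
  A <- igraph::as_adjacency_matrix(g, type = "both", attr = NULL, sparse = FALSE)
  if (!is.null(igraph::E(g)$weight))
    A <- igraph::as_adjacency_matrix(g, type = "both", attr = "weight",
                                     sparse = FALSE)
  A
}

#' Decompose a graph into 2-edge-connected components and bridges
#'
#' Bridges are removed and the remaining connected components of at least two
#' vertices are the 2-edge-connected components (every pair of their vertices
#' lies on a common closed trail).  Vertices in no such component are
#' residual.
#'
#' @param g Undirected graph.
#' @return A list with class `ghac_decomposition`: `components` (list of
#'   induced subgraphs), `bridges` (two-column character matrix of bridge
#'   endpoints), and `residual_nodes` (character vector).
#' @export
bridge_decomposition <- function(g) {
  br <- igraph::bridges(g)
  g2 <- igraph::delete_edges(g, br)
  comp <- igraph::components(g2)
  comps <- list()
  for (k in seq_len(comp$no)) {
    vk <- names(comp$membership)[comp$membership == k]
    if (is.null(vk)) vk <- which(comp$membership == k)
    if (length(vk) >= 2L) {
      comps[[length(comps) + 1L]] <- igraph::induced_subgraph(g, vk)
    }
  }
  # deterministic order: by size desc, then smallest vertex name
  if (length(comps) > 1L) {
    sz <- vapply(comps, igraph::vcount, numeric(1))
    fn <- vapply(comps, function(x) min(igraph::V(x)$name), "")
    comps <- comps[order(-sz, fn)]
  }
  covered <- unlist(lapply(comps, function(x) igraph::V(x)$name))
  res <- setdiff(igraph::V(g)$name, covered)
  bm <- igraph::as_edgelist(g)[as.integer(br), , drop = FALSE]
  structure(list(components = comps, bridges = bm, residual_nodes = res),
            class = "ghac_decomposition")
}

#' Rescale edge weights to the interval `[1, s]`
#'
#' The weighted closed-trail distance assumes similarity weights in `[1, s]`.
#' Arbitrary positive weights are mapped affinely so the minimum becomes 1 and
#' the maximum `s`; if all weights are equal they all become 1.  The map is
#' idempotent for a fixed `s`.
#'
#' @param g Weighted graph with at least one edge.
#' @param s Upper end of the target interval, `s >= 1`.
#' @return The graph with rescaled `weight` attribute.
#' @export
normalize_weights <- function(g, s = 10) {
  if (s < 1) stop("s must be >= 1")
  if (igraph::ecount(g) == 0L) stop("graph has no edges")
  w <- edge_weights(g)
  lo <- min(w); hi <- max(w)
  wn <- if (hi == lo) rep(1, length(w)) else 1 + (w - lo) / (hi - lo) * (s - 1)
  igraph::E(g)$weight <- wn
  g
}

#' Build an undirected trade graph from directed flows
#'
#' Constructs the undirected weighted network used for trade-style data: each
#' directed flow is normalised by its source's trade volume, flows below a
#' relative threshold are dropped, and surviving bilateral pairs are merged
#' into one undirected edge weighted by the mean of the two normalised
#' directional values.  A pair is retained when at least one direction meets
#' the threshold; a present but sub-threshold reverse flow contributes its
#' true normalised value to the mean, an absent one contributes 0.
#'
#' @param flows Data frame with columns `from`, `to`, `weight` (nonnegative
#'   directed flow values).  Duplicated ordered pairs are summed; self-flows
#'   are ignored.
#' @param threshold_fraction Minimum share of the source's volume for a
#'   directed flow to count as significant (default 0.05).
#' @param normalize `"total"` divides by the node's combined in+out volume
#'   (default); `"out"` divides by outgoing volume only.
#' @return Undirected weighted [igraph::igraph] graph.
#' @export
build_undirected_trade_graph <- function(flows, threshold_fraction = 0.05,
                                         normalize = c("total", "out")) {
  normalize <- match.arg(normalize)
  if (threshold_fraction < 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in [0, 1)")
  stopifnot(all(c("from", "to", "weight") %in% names(flows)))
  if (any(flows$weight < 0)) stop("directed flow weights must be nonnegative")
  flows$from <- as.character(flows$from); flows$to <- as.character(flows$to)
  flows <- flows[flows$from != flows$to, , drop = FALSE]
  key <- paste(flows$from, flows$to, sep = "\r")
  agg <- tapply(flows$weight, key, sum)
  pair <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  from <- pair[, 1]; to <- pair[, 2]; val <- as.numeric(agg)

  outvol <- tapply(val, from, sum)
  invol <- tapply(val, to, sum)
  nodes <- union(from, to)
  vol <- setNames(numeric(length(nodes)), nodes)
  if (normalize == "out") {
    vol[names(outvol)] <- outvol
  } else {
    vol[names(outvol)] <- vol[names(outvol)] + outvol
    vol[names(invol)] <- vol[names(invol)] + invol
  }
  denom <- vol[from]
  ok <- denom > 0
  from <- from[ok]; to <- to[ok]; norm <- val[ok] / denom[ok]

  dir_key <- paste(from, to, sep = "\r")
  norm_of <- setNames(norm, dir_key)
  surv <- norm >= threshold_fraction
  ukey <- ifelse(from < to, paste(from, to, sep = "\r"),
                 paste(to, from, sep = "\r"))
  keep_pairs <- unique(ukey[surv])
  if (length(keep_pairs) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  pr <- do.call(rbind, strsplit(keep_pairs, "\r", fixed = TRUE))
  a <- pr[, 1]; b <- pr[, 2]
  fwd <- norm_of[paste(a, b, sep = "\r")]; fwd[is.na(fwd)] <- 0
  rev <- norm_of[paste(b, a, sep = "\r")]; rev[is.na(rev)] <- 0
  w <- (fwd + rev) / 2
  igraph::graph_from_data_frame(
    data.frame(from = a, to = b, weight = as.numeric(w)), directed = FALSE)
}
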