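# Independent brute-force oracles.  These re-derive every quantity from its
# printed definition by exhaustive enumeration, sharing no code with the
# package implementation.

# --- closed-trail distance ------------------------------------------------
# Minimum over pairs of edge-disjoint simple u-v paths of the total edge
# cost (a minimal closed trail through u and v decomposes into two such
# paths).  Edge sets are tracked as bit masks, so graphs must have < 31
# edges.
oracle_all_paths <- function(adj, eid, u, v, n) {
  paths_mask <- integer(0)
  paths_cost <- numeric(0)
  walk <- function(x, visited, mask, cost) {
    if (x == v) {
      paths_mask <<- c(paths_mask, mask)
      paths_cost <<- c(paths_cost, cost)
      return(invisible())
    }
    for (y in adj[[x]]) {
      if (visited[y]) next
      visited[y] <- TRUE
      walk(y, visited, bitwOr(mask, bitwShiftL(1L, eid[x, y])),
           cost + attr(eid, "cost")[eid[x, y] + 1L])
      visited[y] <- FALSE
    }
  }
  visited <- rep(FALSE, n); visited[u] <- TRUE
  walk(u, visited, 0L, 0)
  list(mask = paths_mask, cost = paths_cost)
}

oracle_wct <- function(g, u, v, use_weights = TRUE) {
  labs <- igraph::V(g)$name
  n <- length(labs)
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  stopifnot(m < 31)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, m)
  cost <- if (use_weights) 1 / w else rep(1, m)
  adj <- lapply(seq_len(n), function(i) integer(0))
  eid <- matrix(NA_integer_, n, n)
  for (e in seq_len(m)) {
    a <- el[e, 1]; b <- el[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    eid[a, b] <- e - 1L; eid[b, a] <- e - 1L
  }
  attr(eid, "cost") <- cost
  ui <- match(as.character(u), labs); vi <- match(as.character(v), labs)
  ps <- oracle_all_paths(adj, eid, ui, vi, n)
  if (length(ps$mask) < 2L) return(Inf)
  best <- Inf
  for (i in seq_along(ps$mask)) {
    disjoint <- bitwAnd(ps$mask[i], ps$mask) == 0L
    disjoint[i] <- FALSE
    if (any(disjoint))
      best <- min(best, ps$cost[i] + min(ps$cost[disjoint]))
  }
  best
}

# --- bridges: remove-and-test ---------------------------------------------
oracle_bridges <- function(g) {
  el <- igraph::as_edgelist(g)
  is_bridge <- vapply(seq_len(nrow(el)), function(e) {
    g2 <- igraph::delete_edges(g, e)
    !igraph::are_adjacent(g2, el[e, 1], el[e, 2]) &&
      is.infinite(igraph::distances(g2, el[e, 1], el[e, 2])[1, 1])
  }, TRUE)
  el[is_bridge, , drop = FALSE]
}

# --- maximal cliques: exhaustive subset check -----------------------------
oracle_max_cliques <- function(g) {
  labs <- sort(igraph::V(g)$name)
  n <- length(labs)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  A <- A[labs, labs]
  subsets <- list()
  for (code in seq_len(2^n - 1)) {
    members <- which(bitwAnd(code, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (length(members) < 2L) next
    sub <- A[members, members, drop = FALSE]
    if (!all(sub[upper.tri(sub)])) next
    # complete; maximal iff no outside vertex adjacent to all members
    outside <- setdiff(seq_len(n), members)
    if (any(colSums(A[members, outside, drop = FALSE]) == length(members)))
      next
    subsets[[length(subsets) + 1L]] <- labs[members]
  }
  subsets
}

# --- clique-overlap weight by subset enumeration --------------------------
oracle_overlap_weight <- function(g, overlap) {
  overlap <- as.character(overlap)
  if (length(overlap) < 2L) return(0)
  W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  wtotal <- sum(W) / 2
  labs <- igraph::V(g)$name
  idx <- match(overlap, labs)
  best <- 0
  k <- length(idx)
  for (code in seq_len(2^k - 1)) {
    mem <- idx[bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
    if (length(mem) < 2L) next
    sub <- W[mem, mem, drop = FALSE]
    if (any(sub[upper.tri(sub)] == 0)) next
    val <- length(mem) + sum(sub[upper.tri(sub)]) / wtotal
    if (val > best) best <- val
  }
  best
}

# --- GHAC dissimilarities straight from the formulas ----------------------
oracle_dissimilarity <- function(g, D, a, b, linkage) {
  a <- as.character(a); b <- as.character(b)
  exA <- setdiff(a, b); exB <- setdiff(b, a)
  if (length(exA) == 0L || length(exB) == 0L) return(0)
  ovw <- oracle_overlap_weight(g, intersect(a, b))
  vals <- as.vector(D[exA, exB, drop = FALSE])
  if (linkage == "cl") return(max(vals) / (1 + ovw))
  sum(vals) / (length(union(a, b)) - length(intersect(a, b))) / (1 + ovw)
}

# --- internal quality criteria (naive loops) ------------------------------
oracle_Ocount <- function(cover, labs) {
  vapply(labs, function(v) sum(vapply(cover, function(cm) v %in% cm, TRUE)),
         1L)
}

oracle_me <- function(g, cover) {
  labs <- igraph::V(g)$name
  W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  wdeg <- rowSums(W)
  m2 <- sum(wdeg)
  O <- oracle_Ocount(cover, labs)
  total <- 0
  for (cm in cover) for (i in cm) for (j in cm) {
    ii <- match(i, labs); jj <- match(j, labs)
    total <- total + (W[ii, jj] - wdeg[ii] * wdeg[jj] / m2) / (O[ii] * O[jj])
  }
  unname(total / m2)
}

oracle_mov <- function(g, cover) {
  labs <- igraph::V(g)$name
  W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  A <- W > 0
  wdeg <- rowSums(W)
  O <- oracle_Ocount(cover, labs)
  cover <- cover[vapply(cover, length, 1L) >= 2L]
  terms <- vapply(cover, function(cm) {
    idx <- match(cm, labs)
    s <- 0
    for (i in idx) {
      win <- sum(W[i, idx])
      wout <- wdeg[i] - win
      if (wdeg[i] > 0) s <- s + (win - wout) / (wdeg[i] * O[i])
    }
    ne <- sum(A[idx, idx]) / 2
    s * ne / (length(idx) * choose(length(idx), 2))
  }, 1)
  unname(mean(terms))
}

oracle_cut_scores <- function(g, cover) {
  labs <- igraph::V(g)$name
  W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  A <- W > 0
  n <- length(labs)
  rows <- lapply(cover, function(cm) {
    idx <- match(cm, labs)
    out <- setdiff(seq_len(n), idx)
    ni <- length(idx)
    wcut <- sum(W[idx, out])
    wvol <- sum(W[idx, ])
    volc <- sum(W[out, ])
    int_i <- vapply(idx, function(i) {
      S <- intersect(which(A[i, ]), idx)
      kint <- length(S)
      if (kint < 2) return(0)
      tot <- 0
      for (j in S) for (k in S) if (j != k) tot <- tot + A[j, k]
      tot / (kint * (kint - 1))
    }, 1)
    c(conductance = if (wcut == 0) 0 else if (wvol > 0) wcut / wvol else NA,
      expansion = wcut / ni,
      internal_density = if (ni >= 2) (wvol - wcut) / (ni * (ni - 1)) else NA,
      ratio_cut = if (wcut == 0) 0 else if (ni < n) wcut / (ni * (n - ni)) else NA,
      normalized_cut = if (wcut == 0) 0 else if (wvol > 0 && volc > 0)
        wcut / wvol + wcut / volc else NA,
      fodf = mean(vapply(idx, function(i) sum(W[i, idx]) <= wdeg_i(W, i) / 2,
                         TRUE)),
      internal_transitivity = mean(int_i))
  })
  colMeans(do.call(rbind, rows), na.rm = TRUE)
}
wdeg_i <- function(W, i) sum(W[i, ])

oracle_dunn <- function(g, cover, D, linkage) {
  if (length(cover) < 2L) return(NA_real_)
  diams <- vapply(cover, function(cm) {
    if (length(cm) < 2L) return(NA_real_)
    max(D[cm, cm])
  }, 1)
  if (all(is.na(diams)) || max(diams, na.rm = TRUE) <= 0) return(NA_real_)
  dmin <- Inf
  for (i in seq_len(length(cover) - 1L)) for (j in (i + 1L):length(cover))
    dmin <- min(dmin, oracle_dissimilarity(g, D, cover[[i]], cover[[j]],
                                           linkage))
  unname(dmin / max(diams, na.rm = TRUE))
}

oracle_si <- function(cover, D) {
  covered <- sort(unique(unlist(cover)))
  s <- numeric(length(covered))
  for (vi in seq_along(covered)) {
    v <- covered[vi]
    P <- which(vapply(cover, function(cm) v %in% cm, TRUE))
    nonP <- setdiff(seq_along(cover), P)
    if (length(nonP) == 0L) { s[vi] <- 0; next }
    b <- min(vapply(nonP, function(k)
      mean(D[v, cover[[k]]]), 1))
    terms <- c()
    for (p in P) {
      if (length(cover[[p]]) < 2L) next
      a <- sum(D[v, cover[[p]]]) / (length(cover[[p]]) - 1L)
      terms <- c(terms, (b - a) / max(a, b))
    }
    s[vi] <- if (length(terms)) mean(terms) else 0
  }
  unname(mean(s))
}

# --- external metrics (naive) ---------------------------------------------
oracle_h <- function(p) if (p > 0) -p * log(p) else 0

oracle_onmi <- function(A, B, variant) {
  u <- sort(unique(c(unlist(A), unlist(B))))
  N <- length(u)
  Hx <- function(cm) {
    p <- length(cm) / N
    oracle_h(p) + oracle_h(1 - p)
  }
  cond <- function(X, Y) {
    vapply(seq_along(X), function(i) {
      hxi <- Hx(X[[i]])
      best <- Inf; found <- FALSE
      for (j in seq_along(Y)) {
        n11 <- length(intersect(X[[i]], Y[[j]]))
        n10 <- length(setdiff(X[[i]], Y[[j]]))
        n01 <- length(setdiff(Y[[j]], X[[i]]))
        n00 <- N - n11 - n10 - n01
        if (oracle_h(n11 / N) + oracle_h(n00 / N) <
            oracle_h(n01 / N) + oracle_h(n10 / N)) next
        hj <- Hx(Y[[j]])
        val <- oracle_h(n11 / N) + oracle_h(n10 / N) + oracle_h(n01 / N) +
          oracle_h(n00 / N) - hj
        if (val < best) { best <- val; found <- TRUE }
      }
      if (!found) best <- hxi
      max(0, min(best, hxi))
    }, 1)
  }
  HX <- vapply(A, Hx, 1); HY <- vapply(B, Hx, 1)
  HXgY <- cond(A, B); HYgX <- cond(B, A)
  if (variant == "lfk") {
    t1 <- mean(ifelse(HX > 0, HXgY / HX, 0))
    t2 <- mean(ifelse(HY > 0, HYgX / HY, 0))
    return(1 - (t1 + t2) / 2)
  }
  if (max(sum(HX), sum(HY)) == 0) return(1)
  I <- ((sum(HX) - sum(HXgY)) + (sum(HY) - sum(HYgX))) / 2
  I / max(sum(HX), sum(HY))
}

oracle_f1 <- function(A, B) {
  one <- function(X, Y) {
    mean(vapply(X, function(x) {
      max(vapply(Y, function(y) {
        i <- length(intersect(x, y))
        2 * i / (length(x) + length(y))
      }, 1))
    }, 1))
  }
  (one(A, B) + one(B, A)) / 2
}

oracle_nf1 <- function(P, T) {
  f1s <- numeric(length(P)); match_id <- integer(length(P))
  for (i in seq_along(P)) {
    vals <- vapply(T, function(y) {
      2 * length(intersect(P[[i]], y)) / (length(P[[i]]) + length(y))
    }, 1)
    jacs <- vapply(T, function(y) {
      length(intersect(P[[i]], y)) / length(union(P[[i]], y))
    }, 1)
    cand <- which(vals == max(vals))
    if (length(cand) > 1L) cand <- cand[jacs[cand] == max(jacs[cand])]
    match_id[i] <- cand[1L]; f1s[i] <- vals[cand[1L]]
  }
  coverage <- length(unique(match_id)) / length(T)
  redundancy <- length(P) / length(unique(match_id))
  mean(f1s) * coverage / redundancy
}

oracle_omega <- function(A, B) {
  u <- sort(unique(c(unlist(A), unlist(B))))
  n <- length(u)
  cnt <- function(cover, x, y)
    sum(vapply(cover, function(cm) (x %in% cm) && (y %in% cm), TRUE))
  ta <- c(); tb <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ta <- c(ta, cnt(A, u[i], u[j])); tb <- c(tb, cnt(B, u[i], u[j]))
  }
  np <- length(ta)
  obs <- mean(ta == tb)
  ex <- 0
  for (k in unique(c(ta, tb))) ex <- ex + mean(ta == k) * mean(tb == k)
  if (1 - ex < 1e-12) return(if (obs >= 1 - 1e-12) 1 else 0)
  (obs - ex) / (1 - ex)
}

oracle_onf1 <- function(P, T) {
  ovl <- function(cover) {
    u <- unique(unlist(cover))
    u[vapply(u, function(v)
      sum(vapply(cover, function(cm) v %in% cm, TRUE)) >= 2L, TRUE)]
  }
  p <- ovl(P); t <- ovl(T)
  if (length(p) == 0L && length(t) == 0L) return(1)
  if (length(p) == 0L || length(t) == 0L) return(0)
  tp <- length(intersect(p, t))
  if (tp == 0L) return(0)
  pr <- tp / length(p); rc <- tp / length(t)
  2 * pr * rc / (pr + rc)
}
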