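# Seeded planted-partition benchmark emulating LFR-style weighted graphs:
# power-law degrees (exponent -2) and community sizes (exponent -1), a fixed
# number of overlap nodes with a fixed membership count, degree stubs split
# (1 - mu) intra / mu inter and matched configuration-style, and normal
# edge weights boosted on intra-community edges then rescaled to [1, s].

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Truncated discrete power law p(k) ~ k^-alpha on [kmin, kmax].
rpowerlaw <- function(n, alpha, kmin, kmax) {
  k <- kmin:kmax
  p <- k^(-alpha)
  sample(k, n, replace = TRUE, prob = p / sum(p))
}

powerlaw_mean <- function(alpha, kmin, kmax) {
  k <- kmin:kmax
  p <- k^(-alpha)
  sum(k * p) / sum(p)
}

#' Specify a synthetic benchmark network
#'
#' Parameters mirror the standard planted-partition (LFR-style) setup:
#' `n` nodes, degree distribution with power-law exponent -2, mean
#' `avg_degree` and cap `max_degree`; community sizes with exponent -1 in
#' `[c_min, c_max]`; `on` overlap nodes each belonging to `om` communities;
#' mixing parameter `mu` (fraction of a node's stubs leaving its own
#' communities).  Edge weights are drawn from a normal distribution
#' (`weight_mean`, `weight_sd`), truncated below at `weight_floor`,
#' multiplied by `intra_boost` on intra-community edges, then rescaled to
#' `[1, s]`.
#'
#' @param n Number of nodes.
#' @param avg_degree,max_degree Target mean and maximum degree.
#' @param c_min,c_max Community size range.
#' @param on Number of overlapping nodes.
#' @param om Memberships per overlapping node (`>= 2`).
#' @param mu Mixing parameter in `[0, 1)`.
#' @param weight_mean,weight_sd,weight_floor,intra_boost,s Weight model.
#' @param seed Integer seed; the whole generation is reproducible.
#' @return Object of class `ghac_benchmark_spec`.
#' @export
benchmark_spec <- function(n = 150, avg_degree = 10, max_degree = 30,
                           c_min = 7, c_max = 30, on = 30, om = 2, mu = 0.1,
                           weight_mean = 1, weight_sd = 0.25,
                           weight_floor = 0.05, intra_boost = 2, s = 10,
                           seed = 1) {
  if (mu < 0 || mu >= 1) stop("mu must be in [0, 1)")
  if (on > 0 && om < 2) stop("overlap nodes need om >= 2")
  if (on > n) stop("more overlap nodes than nodes")
  if (c_max > n) stop("c_max exceeds n")
  if (weight_sd < 0 || intra_boost < 1 || s < 1) stop("invalid weight model")
  slots <- n + on * (om - 1)
  if (slots > (n %/% c_min) * c_max && c_min > n)
    stop("memberships cannot be placed with these community sizes")
  structure(list(n = n, avg_degree = avg_degree, max_degree = max_degree,
                 c_min = c_min, c_max = c_max, on = on, om = om, mu = mu,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 weight_floor = weight_floor, intra_boost = intra_boost,
                 s = s, seed = seed),
            class = "ghac_benchmark_spec")
}

# Community sizes from the truncated power law, adjusted to sum to `slots`.
draw_community_sizes <- function(spec, slots) {
  sizes <- integer(0)
  while (sum(sizes) < slots)
    sizes <- c(sizes, rpowerlaw(1, 1, spec$c_min, spec$c_max))
  over <- sum(sizes) - slots
  # shave the excess off the largest communities, never below c_min
  while (over > 0) {
    i <- which.max(sizes)
    cut <- min(over, sizes[i] - spec$c_min)
    if (cut == 0) { # all at c_min: drop one community, redistribute
      sizes <- sizes[-length(sizes)]
      return(draw_community_sizes(spec, slots))
    }
    sizes[i] <- sizes[i] - cut
    over <- over - cut
  }
  if (length(sizes) < max(2L, spec$om))
    return(draw_community_sizes(spec, slots))
  sizes
}

# Assign memberships: processed in decreasing degree order, each node picks
# its communities among those with free capacity, preferring communities
# large enough to host its intra-degree share.
assign_memberships <- function(spec, degrees, sizes) {
  ncomm <- length(sizes)
  capacity <- sizes
  member_of <- vector("list", spec$n)
  is_overlap <- c(rep(TRUE, spec$on), rep(FALSE, spec$n - spec$on))
  ord <- order(-degrees)
  for (v in ord) {
    k <- if (is_overlap[v]) spec$om else 1L
    need <- ceiling((1 - spec$mu) * degrees[v] / k)
    open <- which(capacity > 0)
    if (length(open) < k) return(NULL)
    fit <- open[sizes[open] > need]
    pick <- integer(0)
    pool1 <- fit; pool2 <- setdiff(open, fit)
    for (j in seq_len(k)) {
      pool <- setdiff(if (length(setdiff(pool1, pick))) pool1 else pool2, pick)
      pool <- pool[capacity[pool] > 0]
      if (length(pool) == 0L) return(NULL)
      pick <- c(pick, if (length(pool) == 1L) pool else
        sample(pool, 1, prob = capacity[pool]))
    }
    member_of[[v]] <- sort(pick)
    capacity[pick] <- capacity[pick] - 1L
  }
  member_of
}

# Randomised Havel-Hakimi-style matching: nodes are processed by decreasing
# residual demand and connected to the highest-demand admissible partners
# (random tie-break), so degree demands are realised with few discards.
# `seen` carries edge keys already taken by an earlier phase.
match_demands <- function(demand, forbid_pair = NULL, seen = NULL) {
  if (is.null(seen)) seen <- new.env(parent = emptyenv())
  edges <- list()
  repeat {
    active <- which(demand > 0)
    if (length(active) < 2L) break
    v <- active[which.max(demand[active])]
    cand <- setdiff(active, v)
    cand <- cand[order(-demand[cand], runif(length(cand)))]
    for (u in cand) {
      if (demand[v] == 0L) break
      key <- paste(min(u, v), max(u, v))
      if (!is.null(seen[[key]])) next
      if (!is.null(forbid_pair) && forbid_pair(u, v)) next
      assign(key, TRUE, envir = seen)
      edges[[length(edges) + 1L]] <- c(v, u)
      demand[v] <- demand[v] - 1L; demand[u] <- demand[u] - 1L
    }
    demand[v] <- 0L                     # unplaceable residue is dropped
  }
  list(edges = if (length(edges)) do.call(rbind, edges)
       else matrix(integer(0), ncol = 2),
       seen = seen)
}

#' Generate a synthetic benchmark network
#'
#' @param spec A [benchmark_spec()].
#' @return List with `graph` (weighted igraph, node names `"1".."n"`),
#'   `truth` (list `cover`, `overlap_nodes`), and `audit` (realized mean
#'   degree, realized mean mixing, community sizes).
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "ghac_benchmark_spec"))
  with_seed(spec$seed, {
    # degree sequence: choose the power-law lower cutoff hitting avg_degree
    kmins <- seq_len(spec$max_degree - 1L)
    means <- vapply(kmins, powerlaw_mean, 1, alpha = 2, kmax = spec$max_degree)
    kmin <- kmins[which.min(abs(means - spec$avg_degree))]
    degrees <- rpowerlaw(spec$n, 2, kmin, spec$max_degree)

    slots <- spec$n + spec$on * (spec$om - 1L)
    member_of <- NULL
    for (attempt in 1:50) {
      sizes <- draw_community_sizes(spec, slots)
      member_of <- assign_memberships(spec, degrees, sizes)
      if (!is.null(member_of)) break
    }
    if (is.null(member_of)) stop("could not place community memberships; ",
                                 "spec is too tight")
    ncomm <- length(sizes)
    members <- lapply(seq_len(ncomm), function(k)
      which(vapply(member_of, function(m) k %in% m, TRUE)))

    # split degrees: (1 - mu) intra / mu inter, with stochastic rounding so
    # the expected mixing fraction is exactly mu at every degree
    base <- floor((1 - spec$mu) * degrees)
    intra_deg <- as.integer(base +
      (runif(spec$n) < (1 - spec$mu) * degrees - base))
    inter_deg <- degrees - intra_deg

    # allocate each node's intra demand across its memberships: near-equal
    # split, capped at community size - 1, excess rerouted to slack
    alloc <- matrix(0L, nrow = spec$n, ncol = ncomm)
    for (v in seq_len(spec$n)) {
      ms <- member_of[[v]]
      caps <- vapply(ms, function(k) length(members[[k]]) - 1L, integer(1))
      d <- min(intra_deg[v], sum(caps))
      sh <- rep(d %/% length(ms), length(ms)) +
        (seq_along(ms) <= d %% length(ms))
      over <- pmax(sh - caps, 0L); sh <- pmin(sh, caps)
      extra <- sum(over)
      while (extra > 0L && any(sh < caps)) {
        i <- which(sh < caps)[1L]; sh[i] <- sh[i] + 1L; extra <- extra - 1L
      }
      alloc[v, ms] <- sh
    }
    seen <- new.env(parent = emptyenv())
    edges <- matrix(integer(0), ncol = 2)
    for (k in seq_len(ncomm)) {
      demand <- integer(spec$n)
      demand[members[[k]]] <- alloc[members[[k]], k]
      res <- match_demands(demand, seen = seen)
      edges <- rbind(edges, res$edges)
    }
    share_comm <- function(a, b) length(intersect(member_of[[a]],
                                                  member_of[[b]])) > 0
    res <- match_demands(inter_deg, forbid_pair = share_comm, seen = seen)
    edges <- rbind(edges, res$edges)

    w <- pmax(rnorm(nrow(edges), spec$weight_mean, spec$weight_sd),
              spec$weight_floor)
    intra_edge <- vapply(seq_len(nrow(edges)), function(i)
      share_comm(edges[i, 1], edges[i, 2]), TRUE)
    w[intra_edge] <- w[intra_edge] * spec$intra_boost

    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges[, 1]),
                 to = as.character(edges[, 2]), weight = w),
      directed = FALSE,
      vertices = data.frame(name = as.character(seq_len(spec$n))))
    g <- normalize_weights(g, spec$s)

    cover <- lapply(members, function(mk) as.character(sort(mk)))
    overlap_nodes <- as.character(which(vapply(member_of, length, 1L) >= 2L))
    deg <- igraph::degree(g)
    mixing <- vapply(seq_len(spec$n), function(v) {
      nb <- as.integer(igraph::neighbors(g, as.character(v)))
      if (length(nb) == 0L) return(NA_real_)
      mean(!vapply(nb, function(u) share_comm(v, u), TRUE))
    }, 1)
    list(graph = g,
         truth = list(cover = cover, overlap_nodes = overlap_nodes),
         audit = list(mean_degree = mean(deg),
                      realized_mu = mean(mixing, na.rm = TRUE),
                      community_sizes = vapply(cover, length, 1L),
                      n_edges = igraph::ecount(g)))
  })
}

# Shared per-network harness: detect on the largest 2-edge-connected
# component, score every post-processed level cover internally and against
# the (component-restricted) planted truth.
bench_level_observations <- function(bench, linkage = "al", min_size = 5,
                                     fill = TRUE,
                                     metrics = names(criterion_directions),
                                     qualify = NULL) {
  g <- bench$graph
  dec <- bridge_decomposition(g)
  if (length(dec$components) == 0L) return(NULL)
  gc <- dec$components[[1L]]                 # largest component first
  nodes <- igraph::V(gc)$name
  truth <- lapply(bench$truth$cover, function(cm) intersect(cm, nodes))
  truth <- truth[vapply(truth, length, 1L) >= 2L]
  if (length(truth) < 2L) return(NULL)
  k_true <- length(truth)

  D <- wct_matrix(gc)
  dend <- agglomerate(gc, dist = D, linkage = linkage)
  em <- engine_matrices(gc, D)
  lvls <- level_clusters(dend)
  covers <- lapply(lvls, function(cl)
    postprocess_cover(cl, min_size, fill, gc, em$W))
  counts <- vapply(covers, length, integer(1))
  keep <- counts >= 2L
  if (!is.null(qualify))
    keep <- keep & counts >= qualify[1] * k_true &
      counts <= qualify[2] * k_true
  idx <- which(keep)
  if (length(idx) == 0L) return(NULL)
  rows <- lapply(idx, function(l) {
    cov <- covers[[l]]
    vals <- score_cover_internal(gc, cov, em, metrics, dend$linkage,
                                 dend$al_denominator)
    ext <- suppressWarnings(evaluate_cover(unclass(cov), truth))
    as.data.frame(c(list(level = l - 1L, n_communities = counts[l]),
                    as.list(vals), as.list(ext)))
  })
  do.call(rbind, rows)
}

#' Metric-correlation experiment on synthetic benchmarks
#'
#' For each generated network, every dendrogram level whose post-processed
#' cover has between half and twice the number of planted communities
#' contributes one observation of all internal and external metrics; pooled
#' Spearman rank correlations are reported.
#'
#' @param specs List of [benchmark_spec()] objects (at least 5).
#' @param linkage `"al"` or `"cl"`.
#' @param min_size,fill Cover post-processing options.
#' @param qualify Community-count window relative to the planted count
#'   (default `c(0.5, 2)`).
#' @return List with `external_external` and `external_internal` Spearman
#'   matrices and the pooled `observations` data frame.
#' @export
run_correlation_experiment <- function(specs, linkage = "al", min_size = 5,
                                       fill = TRUE, qualify = c(0.5, 2)) {
  if (length(specs) < 5L) stop("need at least 5 benchmark networks")
  obs <- list()
  for (sp in specs) {
    bench <- generate_benchmark(sp)
    o <- bench_level_observations(bench, linkage, min_size, fill,
                                  qualify = qualify)
    if (is.null(o)) {
      warning("network (seed ", sp$seed, ") had no qualifying levels")
      next
    }
    o$seed <- sp$seed
    obs[[length(obs) + 1L]] <- o
  }
  obs <- do.call(rbind, obs)
  ext_cols <- c("onmi_lfk", "onmi_mgh", "f1", "nf1", "omega", "onf1")
  int_cols <- intersect(names(criterion_directions), names(obs))
  ee <- cor(obs[, ext_cols], method = "spearman", use = "pairwise")
  ei <- cor(obs[, ext_cols], obs[, int_cols], method = "spearman",
            use = "pairwise")
  list(external_external = ee, external_internal = ei, observations = obs)
}

#' Cut-selection experiment: internal criteria vs the best achievable level
#'
#' For each internal criterion, the level optimising it (in its natural
#' direction) is selected per network and the external scores there are
#' compared to the best external score anywhere in the hierarchy ("Top").
#'
#' @inheritParams run_correlation_experiment
#' @param criteria Internal criteria to compare.
#' @param external External metrics to report.
#' @return Data frame: one row per (criterion, external metric) with the
#'   mean selected score, mean top score, and mean gap.
#' @export
run_cut_selection_experiment <- function(specs, linkage = "al",
                                         criteria = c("silhouette", "me",
                                                      "mov", "dunn",
                                                      "conductance"),
                                         external = c("onmi_lfk", "nf1",
                                                      "onf1"),
                                         min_size = 5, fill = TRUE) {
  criteria <- match.arg(criteria, names(criterion_directions),
                        several.ok = TRUE)
  per_net <- list()
  for (sp in specs) {
    bench <- generate_benchmark(sp)
    o <- bench_level_observations(bench, linkage, min_size, fill,
                                  metrics = criteria)
    if (is.null(o)) next
    rows <- list()
    for (cr in criteria) {
      v <- o[[cr]] * criterion_directions[[cr]]
      if (all(is.na(v))) next
      sel <- which(v == max(v, na.rm = TRUE))[1L]
      for (ex in external)
        rows[[length(rows) + 1L]] <- data.frame(
          seed = sp$seed, criterion = cr, external = ex,
          selected = o[[ex]][sel], top = max(o[[ex]], na.rm = TRUE))
    }
    per_net[[length(per_net) + 1L]] <- do.call(rbind, rows)
  }
  all <- do.call(rbind, per_net)
  if (is.null(all)) stop("no network produced valid levels")
  agg <- aggregate(cbind(selected, top) ~ criterion + external, all, mean)
  agg$gap <- agg$top - agg$selected
  agg
}
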