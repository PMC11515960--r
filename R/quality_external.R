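# External agreement metrics between two covers: overlapping NMI (LFK and
# MGH variants), best-match F1 and its normalised variant NF1, the
# chance-corrected Omega index, and the overlapping-node F1 classifier
# score.  The node universe is the union of the nodes of both covers; nodes
# absent from one cover belong to zero communities there.

drop_empty <- function(cover, who) {
  emp <- vapply(cover, length, 1L) == 0L
  if (any(emp)) {
    warning("dropping ", sum(emp), " empty community(ies) from ", who)
    cover <- cover[!emp]
  }
  lapply(cover, function(x) unique(as.character(x)))
}

cover_universe <- function(a, b) sort(unique(c(unlist(a), unlist(b))))

cover_matrix <- function(cover, universe) {
  vapply(cover, function(cm) universe %in% cm, logical(length(universe)))
}

# entropy contribution -p log p, with h(0) = 0
hh <- function(p) ifelse(p > 0, -p * log(p), 0)

# Per-community-pair conditional entropies with the LFK caveat: a community
# matched mostly through complements keeps its unconditional entropy.
onmi_cond_entropy <- function(Ma, Mb) {
  N <- nrow(Ma)
  na <- colSums(Ma); nb <- colSums(Mb)
  n11 <- crossprod(Ma, Mb)                    # |Xi & Yj|
  n10 <- matrix(na, nrow = length(na), ncol = length(nb)) - n11
  n01 <- matrix(nb, nrow = length(na), ncol = length(nb), byrow = TRUE) - n11
  n00 <- N - n11 - n10 - n01
  HX <- hh(na / N) + hh(1 - na / N)            # H(Xi), length |A|
  HYj <- hh(nb / N) + hh(1 - nb / N)           # H(Yj), length |B|
  joint <- hh(n11 / N) + hh(n10 / N) + hh(n01 / N) + hh(n00 / N)
  condm <- sweep(joint, 2, HYj, "-")           # H(Xi|Yj)
  ok <- hh(n11 / N) + hh(n00 / N) >= hh(n01 / N) + hh(n10 / N)
  condm[!ok] <- NA                             # caveat: fall back to H(Xi)
  Hcond <- apply(condm, 1, function(r) if (all(is.na(r))) NA else
    min(r, na.rm = TRUE))
  Hcond[is.na(Hcond)] <- HX[is.na(Hcond)]
  Hcond <- pmin(Hcond, HX)                     # conditioning cannot add info
  list(Hcond = pmax(Hcond, 0), HX = HX)
}

#' Overlapping normalized mutual information
#'
#' Agreement between two covers, 1 for identical covers.  The `"lfk"`
#' variant averages the per-community normalized conditional entropies both
#' ways; the `"mgh"` variant normalizes the (summed) mutual information by
#' the larger of the two cover entropies.  Both apply the standard caveat
#' that a community matched only through complements keeps its unconditional
#' entropy.
#'
#' @param cover_a,cover_b Lists of character vectors.
#' @param variant `"lfk"` or `"mgh"`.
#' @return Value in `[0, 1]`.
#' @export
onmi <- function(cover_a, cover_b, variant = c("lfk", "mgh")) {
  variant <- match.arg(variant)
  a <- drop_empty(cover_a, "cover_a"); b <- drop_empty(cover_b, "cover_b")
  if (length(a) == 0L || length(b) == 0L) stop("covers must be nonempty")
  u <- cover_universe(a, b)
  Ma <- cover_matrix(a, u); Mb <- cover_matrix(b, u)
  ab <- onmi_cond_entropy(Ma, Mb)
  ba <- onmi_cond_entropy(Mb, Ma)
  if (variant == "lfk") {
    norm_term <- function(e) {
      r <- ifelse(e$HX > 0, e$Hcond / e$HX, 0)
      mean(r)
    }
    return(max(0, min(1, 1 - (norm_term(ab) + norm_term(ba)) / 2)))
  }
  HA <- sum(ab$HX); HB <- sum(ba$HX)
  if (max(HA, HB) == 0) return(1)
  I <- ((HA - sum(ab$Hcond)) + (HB - sum(ba$Hcond))) / 2
  max(0, min(1, I / max(HA, HB)))
}

match_f1_one_way <- function(a, b, u) {
  Ma <- cover_matrix(a, u); Mb <- cover_matrix(b, u)
  inter <- crossprod(Ma, Mb)
  sa <- colSums(Ma); sb <- colSums(Mb)
  f1 <- 2 * inter / outer(sa, sb, "+")
  jac <- inter / (outer(sa, sb, "+") - inter)
  best_f1 <- numeric(length(a)); best_j <- integer(length(a))
  for (i in seq_along(a)) {
    # ties on F1 break by larger Jaccard, then lower community id
    cand <- which(f1[i, ] == max(f1[i, ]))
    if (length(cand) > 1L) cand <- cand[jac[i, cand] == max(jac[i, cand])]
    best_j[i] <- cand[1L]
    best_f1[i] <- f1[i, best_j[i]]
  }
  list(f1 = best_f1, match = best_j)
}

#' Best-match F1 between covers
#'
#' Every community is matched to the community of the other cover maximising
#' the set-overlap F1; the score is the symmetrised mean of the best-match
#' F1 values.
#'
#' @inheritParams onmi
#' @return Value in `[0, 1]`.
#' @export
best_match_f1 <- function(cover_a, cover_b) {
  a <- drop_empty(cover_a, "cover_a"); b <- drop_empty(cover_b, "cover_b")
  if (length(a) == 0L || length(b) == 0L) stop("covers must be nonempty")
  u <- cover_universe(a, b)
  (mean(match_f1_one_way(a, b, u)$f1) +
     mean(match_f1_one_way(b, a, u)$f1)) / 2
}

#' Normalized F1 (NF1)
#'
#' Best-match F1 of the predicted communities against the reference,
#' normalized by coverage (fraction of reference communities matched at
#' least once) and redundancy (predicted communities per matched reference
#' community): `NF1 = mean F1 * coverage / redundancy`.  Identical covers
#' score 1.
#'
#' @param cover_pred Predicted cover.
#' @param cover_true Reference cover.
#' @return Value in `[0, 1]`.
#' @export
nf1 <- function(cover_pred, cover_true) {
  p <- drop_empty(cover_pred, "cover_pred")
  t <- drop_empty(cover_true, "cover_true")
  if (length(p) == 0L || length(t) == 0L) stop("covers must be nonempty")
  u <- cover_universe(p, t)
  mw <- match_f1_one_way(p, t, u)
  matched <- unique(mw$match)
  coverage <- length(matched) / length(t)
  redundancy <- length(p) / length(matched)
  max(0, min(1, mean(mw$f1) * coverage / redundancy))
}

#' Omega index
#'
#' Chance-corrected agreement of the number of communities shared by each
#' node pair: `(obs - exp)/(1 - exp)` where `obs` is the fraction of pairs
#' on whose shared-community count the two covers agree and `exp` its
#' expectation under independent permutations.
#'
#' @inheritParams onmi
#' @return Value in `[-1, 1]`; 1 for identical covers, about 0 for
#'   independent ones.
#' @export
omega_index <- function(cover_a, cover_b) {
  a <- drop_empty(cover_a, "cover_a"); b <- drop_empty(cover_b, "cover_b")
  u <- cover_universe(a, b)
  if (length(u) < 2L) stop("need at least 2 nodes")
  Ma <- cover_matrix(a, u); Mb <- cover_matrix(b, u)
  pair_counts <- function(M) {
    S <- tcrossprod(M)                 # shared community count per node pair
    S[upper.tri(S)]
  }
  ta <- pair_counts(Ma); tb <- pair_counts(Mb)
  np <- length(ta)
  obs <- mean(ta == tb)
  lv <- sort(unique(c(ta, tb)))
  exp_ <- sum(vapply(lv, function(k) mean(ta == k) * mean(tb == k), 1))
  if (1 - exp_ < 1e-12) return(if (obs >= 1 - 1e-12) 1 else 0)
  (obs - exp_) / (1 - exp_)
}

#' Overlapping-node F1 (ONF1)
#'
#' F1 of the predicted set of overlapping nodes (`O_v >= 2`) against the
#' true set; both sets empty scores 1 by convention.
#'
#' @inheritParams nf1
#' @return Value in `[0, 1]`.
#' @export
onf1 <- function(cover_pred, cover_true) {
  ov <- function(cover) {
    O <- membership_counts(lapply(cover, unique))
    names(O)[O >= 2L]
  }
  pred <- ov(cover_pred); true <- ov(cover_true)
  if (length(pred) == 0L && length(true) == 0L) return(1)
  if (length(pred) == 0L || length(true) == 0L) return(0)
  tp <- length(intersect(pred, true))
  if (tp == 0L) return(0)
  prec <- tp / length(pred); rec <- tp / length(true)
  2 * prec * rec / (prec + rec)
}

#' All external metrics at once
#'
#' @inheritParams nf1
#' @return Named numeric vector: `onmi_lfk`, `onmi_mgh`, `f1`, `nf1`,
#'   `omega`, `onf1`.
#' @export
evaluate_cover <- function(cover_pred, cover_true) {
  c(onmi_lfk = onmi(cover_pred, cover_true, "lfk"),
    onmi_mgh = onmi(cover_pred, cover_true, "mgh"),
    f1 = best_match_f1(cover_pred, cover_true),
    nf1 = nf1(cover_pred, cover_true),
    omega = omega_index(cover_pred, cover_true),
    onf1 = onf1(cover_pred, cover_true))
}
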