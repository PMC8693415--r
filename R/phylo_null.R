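#' Mean nearest taxon distance (MNTD) of one community
#'
#' For each taxon present in the community, the patristic distance to its
#' nearest other present taxon, averaged either equally (unweighted) or by
#' relative abundance (weighted).
#'
#' @param community named non-negative abundance vector; names are tree
#'   tips. At least 2 taxa must be present.
#' @param tree an \code{ape} phylo with branch lengths.
#' @param abundance_weighted weight nearest-taxon distances by relative
#'   abundance (default TRUE).
#' @return MNTD in the tree's branch-length units.
#' @export
mntd <- function(community, tree, abundance_weighted = TRUE) {
  check_tree(tree)
  if (is.null(names(community))) stop("community vector must be named")
  missing <- setdiff(names(community)[community > 0], tree$tip.label)
  if (length(missing))
    stop("taxa not on tree: ", paste(missing, collapse = ", "))
  community <- community[names(community) %in% tree$tip.label]
  D <- stats::cophenetic(tree)
  idx <- match(names(community), rownames(D))
  .mntd_one(unname(community), D[idx, idx, drop = FALSE], abundance_weighted)
}

.mntd_one <- function(x, D, weighted) {
  present <- which(x > 0)
  if (length(present) < 2L) stop("need at least 2 present taxa")
  sub <- D[present, present, drop = FALSE]
  diag(sub) <- Inf
  nearest <- do.call(pmin, as.data.frame(sub))
  if (weighted) {
    w <- x[present] / sum(x[present])
    sum(w * nearest)
  } else mean(nearest)
}

#' Between-sample mean nearest taxon distance (betaMNTD)
#'
#' For every taxon of one sample, the patristic distance to its nearest
#' taxon in the other sample (a shared taxon has distance zero); the two
#' directed means are averaged. Weighted form uses relative abundances.
#'
#' @param x,y named non-negative abundance vectors over the same taxa.
#' @inheritParams mntd
#' @return betaMNTD >= 0; 0 when the two communities share all their taxa.
#' @export
bmntd <- function(x, y, tree, abundance_weighted = TRUE) {
  check_tree(tree)
  if (is.null(names(x)) || is.null(names(y)))
    stop("community vectors must be named")
  if (!identical(names(x), names(y)))
    stop("communities must be indexed by the same taxa")
  present <- names(x)[x > 0 | y > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("taxa not on tree: ", paste(missing, collapse = ", "))
  if (!any(x > 0) || !any(y > 0)) stop("empty community")
  keep <- names(x) %in% tree$tip.label
  x <- x[keep]; y <- y[keep]
  D <- stats::cophenetic(tree)
  idx <- match(names(x), rownames(D))
  .bmntd_pair(unname(x), unname(y), D[idx, idx, drop = FALSE],
              abundance_weighted)
}

.bmntd_pair <- function(x, y, D, weighted) {
  px <- which(x > 0); py <- which(y > 0)
  near_xy <- do.call(pmin, as.data.frame(D[px, py, drop = FALSE]))
  near_yx <- do.call(pmin, as.data.frame(D[py, px, drop = FALSE]))
  if (weighted) {
    wx <- x[px] / sum(x[px]); wy <- y[py] / sum(y[py])
    0.5 * (sum(wx * near_xy) + sum(wy * near_yx))
  } else 0.5 * (mean(near_xy) + mean(near_yx))
}

# All-pairs betaMNTD for an abundance matrix P (samples x taxa) against a
# taxon distance matrix D. For each sample j, nearmat[, j] holds every
# taxon's distance to its nearest taxon present in j, so the directed sums
# collapse to one matrix product.
.bmntd_matrix <- function(P, D, weighted) {
  n_s <- nrow(P)
  W <- if (weighted) P / rowSums(P) else (P > 0) / rowSums(P > 0)
  nearmat <- vapply(seq_len(n_s), function(j) {
    idx <- which(P[j, ] > 0)
    do.call(pmin, as.data.frame(D[, idx, drop = FALSE]))
  }, numeric(ncol(P)))
  M <- W %*% nearmat          # M[i, j] = directed betaMNTD from i into j
  B <- 0.5 * (M + t(M))
  diag(B) <- 0
  dimnames(B) <- list(rownames(P), rownames(P))
  B
}

.mntd_all <- function(P, D, weighted) {
  vapply(seq_len(nrow(P)), function(i) .mntd_one(P[i, ], D, weighted),
         numeric(1L))
}

#' Nearest taxon index (NTI) per sample
#'
#' Standardized effect size of MNTD against a tip-shuffle null (taxon
#' labels permuted across all tips), signed so that positive NTI means
#' phylogenetic clustering:
#' NTI = (mean(MNTD_null) - MNTD_obs) / sd(MNTD_null).
#'
#' @param table an \code{\link{otu_table}}; every taxon must be a tree tip.
#' @param tree an \code{ape} phylo with branch lengths.
#' @param n_null null repetitions (>= 100 recommended for stable z-scores).
#' @param seed integer seed.
#' @param abundance_weighted weight MNTD by relative abundance.
#' @return named numeric vector of NTI values; NA (with a warning) where
#'   the null standard deviation is zero.
#' @export
nti <- function(table, tree, n_null = 999L, seed = 1L,
                abundance_weighted = TRUE) {
  validate_inputs(table, tree = tree)
  D <- aligned_cophenetic(tree, colnames(table))
  P <- unclass(table)
  obs <- .mntd_all(P, D, abundance_weighted)
  n_taxa <- ncol(P)
  s <- s2 <- numeric(nrow(P))
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      perm <- sample.int(n_taxa)
      v <- .mntd_all(P, D[perm, perm], abundance_weighted)
      s <- s + v
      s2 <- s2 + v * v
    }
  })
  mu <- s / n_null
  sd_null <- sqrt(pmax(0, (s2 - n_null * mu^2) / (n_null - 1L)))
  z <- (mu - obs) / sd_null
  z[sd_null == 0] <- NA_real_
  if (anyNA(z)) warning("NTI undefined (null sd = 0) for sample(s): ",
                        paste(rownames(P)[is.na(z)], collapse = ", "))
  stats::setNames(z, rownames(P))
}

#' betaNTI matrix
#'
#' Standardized effect size of betaMNTD for every sample pair against a
#' tip-shuffle null; the same tip permutation is reused across all pairs
#' within one repetition:
#' betaNTI = (betaMNTD_obs - mean(betaMNTD_null)) / sd(betaMNTD_null).
#' |betaNTI| > 2 flags deterministic turnover (negative: homogeneous
#' selection; positive: variable selection).
#'
#' @inheritParams nti
#' @return symmetric matrix of betaNTI values (diagonal NA); pairs with a
#'   degenerate null (sd = 0) are NA. The observed betaMNTD matrix is
#'   attached as attribute \code{"bmntd_obs"}.
#' @export
bnti_matrix <- function(table, tree, n_null = 999L, seed = 1L,
                        abundance_weighted = TRUE) {
  validate_inputs(table, tree = tree)
  if (nrow(table) < 2L) stop("need at least 2 samples")
  D <- aligned_cophenetic(tree, colnames(table))
  P <- unclass(table)
  obs <- .bmntd_matrix(P, D, abundance_weighted)
  n_taxa <- ncol(P)
  s <- s2 <- matrix(0, nrow(P), nrow(P))
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      perm <- sample.int(n_taxa)
      B <- .bmntd_matrix(P, D[perm, perm], abundance_weighted)
      s <- s + B
      s2 <- s2 + B * B
    }
  })
  mu <- s / n_null
  sd_null <- sqrt(pmax(0, (s2 - n_null * mu^2) / (n_null - 1L)))
  z <- (obs - mu) / sd_null
  z[sd_null == 0] <- NA_real_
  diag(z) <- NA_real_
  dimnames(z) <- dimnames(obs)
  attr(z, "bmntd_obs") <- obs
  attr(z, "n_null") <- as.integer(n_null)
  z
}

# Cophenetic distances reordered to a given taxon order.
aligned_cophenetic <- function(tree, taxa) {
  D <- stats::cophenetic(tree)
  idx <- match(taxa, rownames(D))
  D[idx, idx, drop = FALSE]
}
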