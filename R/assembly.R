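#' Occupancy and abundance pools for the Raup--Crick null model
#'
#' From the sample set under analysis: per-taxon occurrence frequency
#' (fraction of samples containing the taxon) and summed relative
#' abundance across samples.
#'
#' @param counts numeric matrix, samples x taxa.
#' @return list with \code{occupancy} and \code{abundance} vectors.
#' @export
rc_pools <- function(counts) {
  counts <- as.matrix(counts)
  occ <- colMeans(counts > 0)
  rel <- counts / rowSums(counts)
  ab <- colSums(rel)
  list(occupancy = occ, abundance = ab)
}

#' Draw one stochastic-assembly null community
#'
#' Preserves the observed sample's richness and total abundance exactly:
#' richness-many taxa are drawn without replacement with probability
#' proportional to occupancy frequency, each drawn taxon is seated with one
#' individual, and the remaining individuals are assigned by a multinomial
#' draw with probability proportional to pool relative abundance.
#'
#' @param observed non-negative integer abundance vector (one sample).
#' @param pool_occupancy per-taxon occurrence frequency across the sample
#'   pool.
#' @param pool_abundance per-taxon summed relative abundance across the
#'   pool.
#' @return integer abundance vector with the same richness and total as
#'   \code{observed}.
#' @export
rc_null_community <- function(observed, pool_occupancy, pool_abundance) {
  n <- length(observed)
  stopifnot(length(pool_occupancy) == n, length(pool_abundance) == n)
  richness <- sum(observed > 0)
  total <- round(sum(observed))
  candidates <- which(pool_occupancy > 0)
  if (richness > length(candidates))
    stop("observed richness (", richness, ") exceeds pool size (",
         length(candidates), ")")
  # exponential-keys weighted draw without replacement: the taxa with the
  # `richness` smallest Exp(w) keys are a sequential weighted sample
  keys <- stats::rexp(length(candidates)) / pool_occupancy[candidates]
  drawn <- candidates[order(keys)[seq_len(richness)]]
  out <- integer(n)
  out[drawn] <- 1L
  remaining <- total - richness
  if (remaining > 0L) {
    w <- pool_abundance[drawn]
    if (all(w <= 0)) w <- rep(1, length(drawn))
    out[drawn] <- out[drawn] +
      as.integer(stats::rmultinom(1L, remaining, prob = w))
  }
  names(out) <- names(observed)
  out
}

#' Raup--Crick null deviation for one sample pair
#'
#' Compares the observed dissimilarity of a sample pair with dissimilarities
#' of null community pairs drawn by \code{\link{rc_null_community}}:
#' RC = 2 [ (# null < obs) + 0.5 (# ties) ] / reps - 1, in [-1, +1].
#' RC > +0.95 flags dispersal limitation, RC < -0.95 homogenizing
#' dispersal (given |betaNTI| <= 2).
#'
#' @param table an \code{\link{otu_table}}; its samples define the null
#'   pool unless \code{pool} narrows it.
#' @param i,j sample ids or indices.
#' @param metric \code{"bray_curtis"} or \code{"jaccard"}.
#' @param reps null repetitions.
#' @param seed integer master seed; the pair's substream is derived from
#'   it symmetrically, so \code{rc_bray(t, i, j)} equals
#'   \code{rc_bray(t, j, i)}.
#' @param pool optional sample ids defining the regional pool.
#' @return RC value in [-1, 1].
#' @export
rc_bray <- function(table, i, j, metric = c("bray_curtis", "jaccard"),
                    reps = 999L, seed = 1L, pool = rownames(table)) {
  metric <- match.arg(metric)
  counts <- unclass(table)
  if (is.character(i)) i <- match(i, rownames(counts))
  if (is.character(j)) j <- match(j, rownames(counts))
  pools <- rc_pools(counts[pool, , drop = FALSE])
  a <- min(i, j); b <- max(i, j)   # canonical order: RC(i,j) == RC(j,i)
  .rc_pair(counts[a, ], counts[b, ], pools, metric, reps,
           pair_seed(seed, a, b))
}

.dissim <- function(x, y, metric) {
  if (metric == "bray_curtis") bray_curtis(x, y) else jaccard(x, y)
}

.rc_pair <- function(x, y, pools, metric, reps, seed) {
  d_obs <- .dissim(x, y, metric)
  with_seed(seed, {
    below <- ties <- 0L
    for (r in seq_len(reps)) {
      nx <- rc_null_community(x, pools$occupancy, pools$abundance)
      ny <- rc_null_community(y, pools$occupancy, pools$abundance)
      d <- .dissim(nx, ny, metric)
      if (d < d_obs) below <- below + 1L
      else if (d == d_obs) ties <- ties + 1L
    }
  })
  2 * (below + 0.5 * ties) / reps - 1
}

#' Raup--Crick matrix over all sample pairs
#'
#' @inheritParams rc_bray
#' @param samples sample ids to include (pairs are formed within this set).
#' @return symmetric matrix of RC values with NA diagonal.
#' @export
rc_matrix <- function(table, metric = c("bray_curtis", "jaccard"),
                      reps = 999L, seed = 1L, samples = rownames(table),
                      pool = rownames(table)) {
  metric <- match.arg(metric)
  counts <- unclass(table)
  pools <- rc_pools(counts[pool, , drop = FALSE])
  idx <- match(samples, rownames(counts))
  n <- length(idx)
  out <- matrix(NA_real_, n, n, dimnames = list(samples, samples))
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    v <- .rc_pair(counts[idx[a], ], counts[idx[b], ], pools, metric, reps,
                  pair_seed(seed, idx[a], idx[b]))
    out[a, b] <- out[b, a] <- v
  }
  out
}

#' Partition community turnover into five ecological processes
#'
#' The decision tree of the betaNTI / RC framework, with selection checked
#' first: betaNTI < -2 is homogeneous selection and betaNTI > +2 variable
#' selection; only when |betaNTI| <= 2 is RC consulted — RC > +0.95 is
#' dispersal limitation, RC < -0.95 homogenizing dispersal, and anything
#' else drift.
#'
#' @param bnti symmetric betaNTI matrix (or vector).
#' @param rc matching RC matrix (or vector).
#' @return list of class \code{process_partition}: \code{labels}
#'   (per-pair factor, same shape as input), \code{fractions} (named
#'   proportions over classified pairs), \code{n_pairs},
#'   \code{n_excluded} (pairs with undefined betaNTI).
#' @export
partition_processes <- function(bnti, rc) {
  if (!identical(dim(bnti), dim(rc)))
    stop("betaNTI and RC inputs must have the same shape")
  lev <- c("variable_selection", "homogeneous_selection",
           "dispersal_limitation", "homogenizing_dispersal", "drift")
  classify <- function(b, r) {
    if (is.na(b)) return(NA_character_)
    if (b < -2) return("homogeneous_selection")
    if (b > 2) return("variable_selection")
    if (is.na(r)) return(NA_character_)
    if (r > 0.95) return("dispersal_limitation")
    if (r < -0.95) return("homogenizing_dispersal")
    "drift"
  }
  if (is.matrix(bnti)) {
    ut <- upper.tri(bnti)
    lab_vec <- mapply(classify, bnti[ut], rc[ut])
    labels <- matrix(NA_character_, nrow(bnti), ncol(bnti),
                     dimnames = dimnames(bnti))
    labels[ut] <- lab_vec
    labels[lower.tri(labels)] <- t(labels)[lower.tri(labels)]
  } else {
    lab_vec <- mapply(classify, bnti, rc)
    labels <- lab_vec
  }
  classified <- lab_vec[!is.na(lab_vec)]
  fr <- as.numeric(table(factor(classified, levels = lev))) /
    max(1L, length(classified))
  names(fr) <- lev
  structure(list(labels = labels, fractions = fr,
                 n_pairs = length(classified),
                 n_excluded = sum(is.na(lab_vec))),
            class = "process_partition")
}

#' @export
print.process_partition <- function(x, ...) {
  cat("Ecological process partition over", x$n_pairs, "sample pairs")
  if (x$n_excluded) cat(" (", x$n_excluded, " excluded)", sep = "")
  cat("\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Normalized stochasticity ratio (NST) for a sample group
#'
#' For every within-group pair, the observed dissimilarity D is compared
#' with the expected null dissimilarity E (mean over null community pairs
#' drawn by \code{\link{rc_null_community}}): the pair's stochasticity
#' ratio is D/E when D <= E and (1-D)/(1-E) otherwise, and the group NST
#' is 100 x the mean ratio, clamped to [0, 100]. NST > 50% means
#' stochastic processes dominate assembly.
#'
#' @param table an \code{\link{otu_table}}.
#' @param group_samples sample ids forming the group (>= 3).
#' @param metric \code{"bray_curtis"} or \code{"jaccard"}.
#' @param reps null repetitions per pair.
#' @param seed integer master seed (per-pair substreams).
#' @param pool sample ids defining the null pool (default: the group).
#' @return list of class \code{nst_result}: \code{nst} (percent),
#'   \code{pair_ratios}, \code{observed}, \code{expected}, \code{metric},
#'   \code{n_degenerate} (pairs with E exactly 0 or 1, excluded).
#' @export
nst <- function(table, group_samples = rownames(table),
                metric = c("bray_curtis", "jaccard"),
                reps = 1000L, seed = 1L, pool = group_samples) {
  metric <- match.arg(metric)
  if (length(group_samples) < 3L) stop("need a group of at least 3 samples")
  counts <- unclass(table)
  pools <- rc_pools(counts[pool, , drop = FALSE])
  idx <- match(group_samples, rownames(counts))
  if (anyNA(idx)) stop("unknown sample id(s): ",
                       paste(group_samples[is.na(idx)], collapse = ", "))
  pairs <- utils::combn(seq_along(idx), 2L)
  D <- E <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- idx[pairs[1L, k]]; b <- idx[pairs[2L, k]]
    x <- counts[a, ]; y <- counts[b, ]
    D[k] <- .dissim(x, y, metric)
    E[k] <- with_seed(pair_seed(seed, a, b), {
      mean(vapply(seq_len(reps), function(r) {
        .dissim(rc_null_community(x, pools$occupancy, pools$abundance),
                rc_null_community(y, pools$occupancy, pools$abundance),
                metric)
      }, numeric(1L)))
    })
  }
  degen <- E <= 0 | E >= 1
  ratio <- ifelse(D <= E, D / E, (1 - D) / (1 - E))
  ratio[degen] <- NA_real_
  value <- 100 * mean(ratio, na.rm = TRUE)
  structure(list(nst = min(100, max(0, value)),
                 pair_ratios = ratio, observed = D, expected = E,
                 metric = metric, reps = reps,
                 n_degenerate = sum(degen)),
            class = "nst_result")
}

#' @export
print.nst_result <- function(x, ...) {
  cat(sprintf("NST (%s): %.2f%% over %d pairs", x$metric, x$nst,
              length(x$pair_ratios)))
  if (x$n_degenerate) cat(" (", x$n_degenerate, " degenerate excluded)",
                          sep = "")
  cat("\n")
  invisible(x)
}
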