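#' Principal-coordinate analysis (classical scaling)
#'
#' Double-centers -1/2 D^2 and eigen-decomposes it. Coordinates are
#' returned for positive-eigenvalue axes only; negative eigenvalues are
#' retained in the report (they flag non-Euclidean input) but excluded from
#' coordinates and from the proportion of variance explained.
#'
#' @param dm symmetric dissimilarity matrix with zero diagonal.
#' @return list of class \code{pcoa_result}: \code{coordinates}
#'   (samples x axes), \code{eigenvalues} (all, decreasing),
#'   \code{proportion_explained} (per positive axis).
#' @export
pcoa <- function(dm) {
  check_dm(dm)
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 samples")
  # Gower double-centering of -D^2/2, then eigendecomposition
  A <- -0.5 * dm^2
  B <- A - rowMeans(A)
  B <- t(t(B) - colMeans(B)) + mean(A)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  eig <- e$values
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig[pos]),
                                                    length(pos))
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 proportion_explained = eig[pos] / sum(eig[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "positive axes\n")
  pe <- round(100 * x$proportion_explained[seq_len(min(3L, length(x$proportion_explained)))], 1)
  cat("Variance explained (first axes):", paste0(pe, "%", collapse = ", "), "\n")
  invisible(x)
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Anderson's pseudo-F from among/within sums of squared dissimilarities,
#' with a free-permutation p-value. Delegates to \code{vegan::adonis2}.
#'
#' @param dm symmetric dissimilarity matrix.
#' @param groups group labels, one per sample (in \code{dm} row order).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return list of class \code{permutation_test}: statistic name, value,
#'   p-value, permutation count.
#' @export
permanova <- function(dm, groups, n_perm = 999L, seed = 1L) {
  groups <- check_groups(dm, groups)
  fit <- with_seed(seed, {
    df <- data.frame(grp = groups)
    vegan::adonis2(stats::as.dist(dm) ~ grp, data = df,
                   permutations = n_perm)
  })
  permutation_test("pseudo-F", fit$F[1L], fit$`Pr(>F)`[1L], n_perm)
}

#' Multiple-response permutation procedure (MRPP)
#'
#' delta = weighted mean within-group dissimilarity (weights n_g/N); the
#' p-value is lower-tail (small delta means cohesive groups). Delegates to
#' \code{vegan::mrpp}.
#'
#' @inheritParams permanova
#' @return a \code{permutation_test} with statistic \code{"delta"}.
#' @export
mrpp <- function(dm, groups, n_perm = 999L, seed = 1L) {
  groups <- check_groups(dm, groups)
  fit <- with_seed(seed,
    vegan::mrpp(stats::as.dist(dm), groups, permutations = n_perm,
                weight.type = 1))
  permutation_test("delta", fit$delta, fit$Pvalue, n_perm)
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Distances from each sample to its group centroid in principal-coordinate
#' space (imaginary axes handled by subtracting squared distances on
#' negative-eigenvalue axes), compared across groups by a permuted one-way
#' F test on raw group labels. Delegates to \code{vegan::betadisper} and
#' \code{vegan::permutest}.
#'
#' @inheritParams permanova
#' @return a \code{permutation_test} with statistic \code{"F"}; the
#'   per-group mean distances to centroid are attached as
#'   \code{group_means}.
#' @export
permdisp <- function(dm, groups, n_perm = 999L, seed = 1L) {
  groups <- check_groups(dm, groups)
  mod <- vegan::betadisper(stats::as.dist(dm), groups, type = "centroid")
  pt <- with_seed(seed, vegan::permutest(mod, permutations = n_perm))
  res <- permutation_test("F", pt$tab$F[1L], pt$tab$`Pr(>F)`[1L], n_perm)
  res$group_means <- tapply(mod$distances, groups, mean)
  res
}

#' Null-model dispersion test
#'
#' Compares the observed mean distance-to-centroid of a sample set with
#' the dispersion of stochastic-assembly null communities (the same
#' richness- and abundance-preserving null used by the Raup--Crick
#' machinery). One null community is generated per observed sample per
#' repetition; the test statistic is the PERMDISP F between the pooled
#' observed and null sets.
#'
#' @param table an \code{\link{otu_table}}.
#' @param samples sample ids to analyse (default: all).
#' @param metric \code{"bray_curtis"} or \code{"jaccard"}.
#' @param reps null repetitions.
#' @param n_perm permutations for the PERMDISP p-value.
#' @param seed integer seed.
#' @return list of class \code{null_dispersion}: \code{actual_centroid},
#'   \code{null_centroid}, \code{F}, \code{p}.
#' @export
null_dispersion_test <- function(table, samples = rownames(table),
                                 metric = c("bray_curtis", "jaccard"),
                                 reps = 30L, n_perm = 999L, seed = 1L) {
  metric <- match.arg(metric)
  if (length(samples) < 3L) stop("need at least 3 samples")
  obs <- unclass(table)[samples, , drop = FALSE]
  pools <- rc_pools(obs)
  nulls <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(reps), function(r) {
      t(vapply(seq_len(nrow(obs)), function(i)
        rc_null_community(obs[i, ], pools$occupancy, pools$abundance),
        numeric(ncol(obs))))
    }))
  })
  rownames(nulls) <- sprintf("null_r%d_s%d",
                             rep(seq_len(reps), each = nrow(obs)),
                             rep(seq_len(nrow(obs)), reps))
  all_m <- rbind(obs, nulls)
  dm <- distance_matrix(otu_table(all_m), metric)
  labels <- c(rep("observed", nrow(obs)), rep("null", nrow(nulls)))
  mod <- vegan::betadisper(stats::as.dist(dm), labels, type = "centroid")
  pt <- with_seed(seed + 1L, vegan::permutest(mod, permutations = n_perm))
  means <- tapply(mod$distances, labels, mean)
  structure(list(actual_centroid = unname(means["observed"]),
                 null_centroid = unname(means["null"]),
                 F = pt$tab$F[1L], p = pt$tab$`Pr(>F)`[1L],
                 metric = metric, reps = reps),
            class = "null_dispersion")
}

#' @export
print.null_dispersion <- function(x, ...) {
  cat("Null-model dispersion test (", x$metric, ")\n", sep = "")
  cat(sprintf("  actual centroid %.4f  null centroid %.4f  F %.3f  P %.4g\n",
              x$actual_centroid, x$null_centroid, x$F, x$p))
  invisible(x)
}

permutation_test <- function(name, statistic, p, n_perm) {
  structure(list(statistic_name = name, statistic = unname(statistic),
                 p_value = unname(p), n_permutations = as.integer(n_perm)),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("%s = %.4f, P = %.4g (%d permutations)\n",
              x$statistic_name, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

check_groups <- function(dm, groups) {
  check_dm(dm)
  if (length(groups) != nrow(dm))
    stop("one group label per sample is required")
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  groups
}
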