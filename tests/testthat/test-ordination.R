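test_that("PCoA reproduces Euclidean configurations exactly", {
  set.seed(4)
  X <- cbind(rnorm(9), rnorm(9))
  rownames(X) <- paste0("s", 1:9)
  dm <- as.matrix(dist(X))
  ord <- pcoa(dm)
  # all pairwise distances reproduced in the embedding
  d2 <- as.matrix(dist(ord$coordinates))
  expect_lt(max(abs(d2 - dm)), 1e-8)
  # Procrustes error against the generating configuration
  pr <- vegan::procrustes(X, ord$coordinates[, 1:2], symmetric = TRUE)
  expect_lt(pr$ss, 1e-8)
  # points on a line: first axis carries everything
  L <- matrix(c(0, 1, 3, 7), dimnames = list(paste0("s", 1:4), NULL))
  ordL <- pcoa(as.matrix(dist(L)))
  expect_lt(max(abs(as.matrix(dist(ordL$coordinates[, 1])) -
                    as.matrix(dist(L)))), 1e-8)
  expect_equal(ordL$proportion_explained[1], 1)
})

test_that("PCoA of an equidistant design has equal positive eigenvalues", {
  n <- 5
  dm <- matrix(1, n, n) - diag(n)
  dimnames(dm) <- list(paste0("s", 1:n), paste0("s", 1:n))
  ord <- pcoa(dm)
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-10]
  expect_equal(max(pos) - min(pos), 0, tolerance = 1e-10)
})

test_that("PERMANOVA flags perfect separation at the permutation floor", {
  set.seed(77)
  counts <- rbind(cbind(matrix(rpois(24, 8), 6), matrix(0, 6, 4)),
                  cbind(matrix(0, 6, 4), matrix(rpois(24, 8), 6)))
  tab <- small_table(counts)
  dm <- distance_matrix(tab)
  g <- rep(c("a", "b"), each = 6)
  res <- permanova(dm, g, n_perm = 199, seed = 1)
  # disjoint supports: observed pseudo-F beats (almost) every permutation
  expect_lte(res$p_value, 2 / 200)
  expect_gt(res$statistic, 1)
  # invariant to relabeling of groups
  res2 <- permanova(dm, rep(c("x", "y"), each = 6), n_perm = 199, seed = 1)
  expect_equal(res2$statistic, res$statistic)
  expect_error(permanova(dm, c(rep("a", 11), "b"), 99, 1), "fewer than 2")
})

test_that("MRPP delta is small for cohesive groups and label-invariant", {
  set.seed(78)
  counts <- rbind(cbind(matrix(rpois(24, 8), 6), matrix(0, 6, 4)),
                  cbind(matrix(0, 6, 4), matrix(rpois(24, 8), 6)))
  tab <- small_table(counts)
  dm <- distance_matrix(tab)
  g <- rep(c("a", "b"), each = 6)
  res <- mrpp(dm, g, n_perm = 199, seed = 2)
  expect_lte(res$p_value, 2 / 200)
  expect_equal(res$statistic_name, "delta")
  # delta equals the group-size-weighted mean within-group dissimilarity
  wa <- dm[1:6, 1:6][lower.tri(dm[1:6, 1:6])]
  wb <- dm[7:12, 7:12][lower.tri(dm[7:12, 7:12])]
  expect_equal(res$statistic, mean(c(mean(wa), mean(wb))), tolerance = 1e-12)
  res2 <- mrpp(dm, rep(c("B", "A"), each = 6), n_perm = 199, seed = 2)
  expect_equal(res2$statistic, res$statistic)
})

test_that("PERMDISP detects unequal dispersion and not equal dispersion", {
  set.seed(31)
  rej_equal <- rej_unequal <- logical(15)
  for (i in seq_len(15)) {
    tight <- matrix(rnorm(12, sd = 1), 6, 2)
    wide <- matrix(rnorm(12, sd = 5), 6, 2)
    same <- matrix(rnorm(12, sd = 1), 6, 2)
    ids <- paste0("s", 1:12)
    d_un <- as.matrix(dist(rbind(tight, wide))); dimnames(d_un) <- list(ids, ids)
    d_eq <- as.matrix(dist(rbind(tight, same))); dimnames(d_eq) <- list(ids, ids)
    g <- rep(c("a", "b"), each = 6)
    rej_unequal[i] <- permdisp(d_un, g, n_perm = 199, seed = i)$p_value <= 0.05
    rej_equal[i] <- permdisp(d_eq, g, n_perm = 199, seed = i)$p_value <= 0.05
  }
  expect_gte(mean(rej_unequal), 0.8)
  expect_lte(mean(rej_equal), 0.3)
})

test_that("group distances to centroid are equal on an equilateral simplex", {
  n <- 4
  dm <- matrix(1, n, n) - diag(n)
  dimnames(dm) <- list(paste0("s", 1:n), paste0("s", 1:n))
  mod <- vegan::betadisper(stats::as.dist(dm), rep("g", n), type = "centroid")
  expect_equal(max(mod$distances) - min(mod$distances), 0, tolerance = 1e-10)
})

test_that("the null dispersion test contrasts observed and null spread", {
  # artificially identical samples: zero observed dispersion, null > 0
  counts <- matrix(rep(c(30, 10, 5, 3, 2), each = 6), 6)
  tab <- small_table(counts)
  res <- null_dispersion_test(tab, metric = "bray_curtis", reps = 10,
                              n_perm = 99, seed = 3)
  expect_equal(res$actual_centroid, 0, tolerance = 1e-12)
  expect_gt(res$null_centroid, 0)
  expect_lte(res$p, 0.05)
  expect_true(is.finite(res$F))
  # all four fields populated on ordinary data too
  ds <- tiny_dataset(seed = 17, n_samples = 2)
  r2 <- null_dispersion_test(ds$table, metric = "jaccard", reps = 5,
                             n_perm = 49, seed = 4)
  expect_true(all(vapply(r2[c("actual_centroid", "null_centroid", "F", "p")],
                         is.finite, logical(1))))
})

test_that("permutation p-values respect the add-one granularity", {
  ds <- tiny_dataset(seed = 19, n_samples = 3)
  dm <- distance_matrix(ds$table)
  g <- ds$metadata$gut_region
  for (fit in list(permanova(dm, g, n_perm = 49, seed = 5),
                   mrpp(dm, g, n_perm = 49, seed = 5),
                   permdisp(dm, g, n_perm = 49, seed = 5))) {
    expect_gte(fit$p_value, 1 / 50)
    expect_lte(fit$p_value, 1)
    expect_equal((fit$p_value * 50) %% 1, 0, tolerance = 1e-9)
  }
})
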