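test_that("MNTD matches closed forms on simple trees", {
  st <- star_tree(5, b = 2)
  x <- c(t1 = 3, t2 = 0, t3 = 1, t4 = 0, t5 = 0)
  expect_equal(mntd(x, st), 4)                       # star: always 2b
  expect_equal(mntd(x, st, abundance_weighted = FALSE), 4)
  ct <- caterpillar_tree()
  y <- c(t1 = 1, t2 = 1, t3 = 0, t4 = 0)
  expect_equal(mntd(y, ct), 3)                       # two taxa: their distance
  expect_error(mntd(c(t1 = 1, t2 = 0, t3 = 0, t4 = 0), ct), "2 present")
})

test_that("MNTD and betaMNTD equal the brute-force oracle on random instances", {
  for (seed in 1:60) {
    inst <- random_instance(seed)
    D <- stats::cophenetic(inst$tree)[colnames(inst$table), colnames(inst$table)]
    P <- unclass(inst$table)
    for (w in c(TRUE, FALSE)) {
      for (i in seq_len(nrow(P)))
        expect_equal(mntd(P[i, ], inst$tree, w), bf_mntd(P[i, ], D, w),
                     tolerance = 1e-12)
      for (i in seq_len(nrow(P) - 1)) for (j in (i + 1):nrow(P))
        expect_equal(bmntd(P[i, ], P[j, ], inst$tree, w),
                     bf_bmntd(P[i, ], P[j, ], D, w), tolerance = 1e-12)
    }
  }
})

test_that("betaMNTD is symmetric, zero for identical communities", {
  inst <- random_instance(99)
  P <- unclass(inst$table)
  expect_equal(bmntd(P[1, ], P[1, ], inst$tree), 0)
  expect_equal(bmntd(P[1, ], P[2, ], inst$tree),
               bmntd(P[2, ], P[1, ], inst$tree))
})

test_that("phylogenetic distances agree with picante's implementations", {
  skip_if_not_installed("picante")
  for (seed in 1:10) {
    inst <- random_instance(seed + 500, max_taxa = 8L, max_samples = 4L)
    P <- unclass(inst$table)
    ref_w <- as.matrix(picante::comdistnt(P, stats::cophenetic(inst$tree),
                                          abundance.weighted = TRUE))
    ref_m <- picante::mntd(P, stats::cophenetic(inst$tree),
                           abundance.weighted = TRUE)
    for (i in seq_len(nrow(P) - 1)) for (j in (i + 1):nrow(P))
      expect_equal(bmntd(P[i, ], P[j, ], inst$tree), ref_w[i, j],
                   tolerance = 1e-10)
    for (i in seq_len(nrow(P)))
      expect_equal(mntd(P[i, ], inst$tree), ref_m[i], tolerance = 1e-10)
  }
})

test_that("NTI detects clustering with the mandated sign convention", {
  # ten small clades hanging off deep branches; a community occupying
  # three whole clades is strongly clustered relative to a tip shuffle
  clade <- function(i) sprintf("(t%d_1:1,t%d_2:1,t%d_3:1):20", i, i, i)
  tree <- ape::read.tree(text = paste0("(", paste(vapply(1:10, clade, ""),
                                                  collapse = ","), ");"))
  clustered <- as.numeric(grepl("^t[123]_", tree$tip.label))
  spread <- as.numeric(grepl("_1$", tree$tip.label))  # one tip per clade
  counts <- rbind(clustered = clustered, spread = spread)
  colnames(counts) <- tree$tip.label
  z <- nti(otu_table(counts), tree, n_null = 200, seed = 8)
  expect_gt(z[["clustered"]], 2)      # positive = clustered
  expect_lt(z[["spread"]], 0)         # overdispersed community
  # all-tips community: every shuffle is identical, flagged undefined
  fullm <- rbind(all = rep(1, 30), half = clustered)
  colnames(fullm) <- tree$tip.label
  expect_warning(z2 <- nti(otu_table(fullm), tree, n_null = 100, seed = 1),
                 "undefined")
  expect_true(is.na(z2[["all"]]))
})

test_that("NTI is approximately standard under its own null", {
  set.seed(14)
  tree <- ape::rtree(40)
  counts <- t(replicate(30, {
    x <- numeric(40)
    x[sample(40, 12)] <- rpois(12, 4) + 1
    x
  }))
  dimnames(counts) <- list(paste0("s", 1:30), tree$tip.label)
  z <- nti(otu_table(counts), tree, n_null = 200, seed = 3)
  expect_gte(mean(abs(z) <= 2), 0.9)
})

test_that("betaNTI matrices are symmetric, reproducible and sign-correct", {
  ds <- tiny_dataset(seed = 23, n_taxa = 30, n_samples = 2,
                     community_size = 400)
  b1 <- bnti_matrix(ds$table, ds$tree, n_null = 100, seed = 5)
  b2 <- bnti_matrix(ds$table, ds$tree, n_null = 100, seed = 5)
  expect_identical(b1, b2)                     # bit-identical per seed
  expect_equal(unclass(b1), t(unclass(b1)))
  expect_true(all(is.na(diag(b1))))
  # identical samples share every taxon under every tip shuffle, so the
  # null has zero spread: observed betaMNTD is 0 and the pair is flagged
  # undefined rather than given an arbitrary z-score
  counts <- rbind(a = c(5, 3, 2, 1, 0, 0, 4, 0), b = c(5, 3, 2, 1, 0, 0, 4, 0),
                  c = c(0, 0, 1, 2, 6, 3, 0, 1))
  set.seed(2)
  tree <- ape::rtree(8)
  colnames(counts) <- tree$tip.label
  b3 <- bnti_matrix(otu_table(counts), tree, n_null = 100, seed = 1)
  expect_equal(attr(b3, "bmntd_obs")["a", "b"], 0)
  expect_true(is.na(b3["a", "b"]))
  expect_false(is.na(b3["a", "c"]))
})
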