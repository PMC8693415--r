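test_that("the RC null community preserves richness and total abundance", {
  set.seed(6)
  for (rep in 1:30) {
    n <- sample(5:20, 1)
    obs <- rpois(n, 3)
    if (sum(obs > 0) < 2) next
    occ <- runif(n); ab <- rgamma(n, 1)
    null <- rc_null_community(obs, occ, ab)
    expect_equal(sum(null > 0), sum(obs > 0))
    expect_equal(sum(null), round(sum(obs)))
  }
  # pool exactly as large as the observed richness: forced draw
  obs <- c(4, 2, 1)
  null <- rc_null_community(obs, c(0.5, 0.2, 0.9), c(1, 1, 1))
  expect_true(all(null > 0))
  expect_error(rc_null_community(c(1, 1), c(0.5, 0), c(1, 1)), "richness")
})

test_that("taxon draws follow the occupancy weights", {
  # richness-1 draws make inclusion probability exactly proportional
  occ <- c(0.1, 0.2, 0.3, 0.4)
  set.seed(9)
  hits <- integer(4)
  for (i in 1:4000) {
    null <- rc_null_community(c(5, 0, 0, 0), occ, rep(1, 4))
    hits <- hits + (null > 0)
  }
  gof <- stats::chisq.test(hits, p = occ / sum(occ))
  expect_gt(gof$p.value, 0.001)
})

test_that("the exponential-keys draw matches sequential weighted sampling", {
  # same distribution as R's sequential weighted sampling without
  # replacement (independent oracle), checked on marginal inclusion rates
  occ <- c(5, 3, 1, 1, 0.5, 2)
  set.seed(11)
  ours <- integer(6); ref <- integer(6)
  for (i in 1:4000) {
    null <- rc_null_community(c(1, 1, 1, 0, 0, 0), occ, rep(1, 6))
    ours <- ours + (null > 0)
    picks <- sample.int(6, 3, prob = occ)
    ref[picks] <- ref[picks] + 1L
  }
  expect_gt(suppressWarnings(stats::chisq.test(rbind(ours, ref))$p.value),
            0.001)
})

test_that("RC is -1 for identical pairs, bounded, symmetric, reproducible", {
  counts <- rbind(a = c(10, 5, 3, 0, 0, 2), b = c(10, 5, 3, 0, 0, 2),
                  c = c(0, 2, 8, 4, 1, 0), d = c(3, 0, 0, 7, 5, 1),
                  e = c(1, 6, 0, 0, 8, 2))
  colnames(counts) <- paste0("t", 1:6)
  tab <- otu_table(counts)
  expect_equal(rc_bray(tab, "a", "b", reps = 199, seed = 4), -1)
  expect_equal(rc_bray(tab, "a", "c", reps = 99, seed = 4),
               rc_bray(tab, "c", "a", reps = 99, seed = 4))
  expect_identical(rc_bray(tab, "c", "d", reps = 99, seed = 4),
                   rc_bray(tab, "c", "d", reps = 99, seed = 4))
  rcm <- rc_matrix(tab, reps = 49, seed = 4)
  off <- rcm[upper.tri(rcm)]
  expect_true(all(off >= -1 & off <= 1))
  expect_equal(rcm, t(rcm))
  expect_equal(rcm["a", "c"], rc_bray(tab, "a", "c", reps = 49, seed = 4))
})

test_that("process partitioning follows the published decision tree", {
  # selection outranks RC; RC splits the stochastic side
  cases <- list(
    list(b = -3, r = 0.99, lab = "homogeneous_selection"),
    list(b = 3, r = -0.99, lab = "variable_selection"),
    list(b = 0, r = 0.99, lab = "dispersal_limitation"),
    list(b = 0, r = -0.99, lab = "homogenizing_dispersal"),
    list(b = 0, r = 0, lab = "drift"),
    list(b = 2, r = 0.95, lab = "drift"),       # boundaries are inclusive
    list(b = -2, r = -0.95, lab = "drift"))
  for (cs in cases) {
    p <- partition_processes(cs$b, cs$r)
    expect_equal(unname(p$labels), cs$lab)
    expect_equal(sum(p$fractions), 1)
    expect_equal(unname(p$fractions[cs$lab]), 1)
  }
})

test_that("partition fractions sum to one and undefined pairs are excluded", {
  set.seed(12)
  n <- 8
  b <- matrix(rnorm(n * n, sd = 2), n, n); b <- (b + t(b)) / 2; diag(b) <- NA
  r <- matrix(runif(n * n, -1, 1), n, n); r <- (r + t(r)) / 2; diag(r) <- NA
  b[1, 2] <- b[2, 1] <- NA    # an undefined betaNTI pair
  p <- partition_processes(b, r)
  expect_equal(sum(p$fractions), 1, tolerance = 1e-12)
  expect_equal(p$n_pairs + p$n_excluded, n * (n - 1) / 2)
  expect_equal(p$n_excluded, 1)
  expect_equal(p$labels, t(p$labels))
})

test_that("NST is zero for identical samples and well-behaved otherwise", {
  counts <- rbind(a = c(10, 5, 3, 2, 1), b = c(10, 5, 3, 2, 1),
                  c = c(10, 5, 3, 2, 1), d = c(2, 1, 10, 5, 3),
                  e = c(1, 2, 3, 10, 5))
  colnames(counts) <- paste0("t", 1:5)
  tab <- otu_table(counts)
  res <- nst(tab, c("a", "b", "c"), reps = 100, seed = 7,
             pool = rownames(tab))
  expect_equal(res$nst, 0)
  expect_true(all(res$observed == 0))
  expect_true(all(res$expected > 0))
  ds <- tiny_dataset(seed = 31, n_samples = 2)
  g <- ds$metadata$sample_id[ds$metadata$group == ds$metadata$group[1]]
  r2 <- nst(ds$table, rownames(ds$table)[1:4], reps = 50, seed = 2)
  expect_gte(r2$nst, 0); expect_lte(r2$nst, 100)
  expect_identical(r2$nst, nst(ds$table, rownames(ds$table)[1:4],
                               reps = 50, seed = 2)$nst)
  expect_error(nst(tab, c("a", "b")), "at least 3")
})

test_that("a group generated by the null model itself scores as stochastic", {
  counts <- rbind(a = c(9, 4, 3, 2, 1, 1, 0, 0), b = c(0, 6, 5, 1, 0, 3, 4, 1),
                  c = c(5, 0, 2, 6, 2, 0, 3, 2), d = c(3, 3, 0, 4, 6, 2, 0, 2))
  colnames(counts) <- paste0("t", 1:8)
  pools <- rc_pools(counts)
  set.seed(15)
  null_tab <- t(sapply(1:6, function(i)
    rc_null_community(counts[(i - 1) %% 4 + 1, ], pools$occupancy,
                      pools$abundance)))
  rownames(null_tab) <- paste0("n", 1:6)
  res <- nst(otu_table(null_tab), reps = 200, seed = 3)
  expect_gt(res$nst, 50)
})

test_that("community_assembly fits, summarizes and plots", {
  ds <- tiny_dataset(seed = 41, n_taxa = 30, n_samples = 3,
                     community_size = 500)
  keep <- ds$metadata$gut_region == "jejunum"
  tab <- otu_table(unclass(ds$table)[keep, ])
  fit <- community_assembly(tab, ds$tree, ds$metadata[keep, ],
                            group = "diet_group", n_null = 60,
                            rc_reps = 60, seed = 3)
  expect_s3_class(fit, "community_assembly")
  expect_equal(dim(fit$bnti), c(12, 12))
  expect_equal(sum(fit$partition$fractions), 1)
  expect_equal(nrow(fit$group_nst), 4)
  expect_true(all(fit$group_nst$nst_bray >= 0 & fit$group_nst$nst_bray <= 100))
  expect_equal(unname(rowSums(fit$group_fractions)), rep(1, 4))
  s <- summary(fit)
  expect_true(is.finite(s$mean_bnti))
  expect_output(print(s), "Process fractions")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
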