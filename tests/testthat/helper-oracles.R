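# Shared fixtures and independent brute-force oracles for the null-model
# statistics. Oracles are deliberately naive (explicit loops over pairs)
# so they cannot share a code path with the implementation.

star_tree <- function(n, b = 1) {
  ape::read.tree(text = paste0("(", paste0("t", seq_len(n), ":", b,
                                           collapse = ","), ");"))
}

caterpillar_tree <- function() {
  # ((t1:1,t2:2):3,(t3:4,t4:5):6);
  ape::read.tree(text = "((t1:1,t2:2):3,(t3:4,t4:5):6);")
}

small_table <- function(counts, samples = NULL, taxa = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- samples %||% paste0("s", seq_len(nrow(counts)))
  colnames(counts) <- taxa %||% paste0("t", seq_len(ncol(counts)))
  otu_table(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_instance <- function(seed, max_taxa = 6L, max_samples = 4L) {
  set.seed(seed)
  n_taxa <- sample(3:max_taxa, 1L)
  n_samp <- sample(2:max_samples, 1L)
  tree <- ape::rtree(n_taxa)
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  counts <- matrix(rpois(n_samp * n_taxa, 3), n_samp, n_taxa)
  # guarantee >= 2 present taxa per sample
  for (i in seq_len(n_samp)) {
    while (sum(counts[i, ] > 0) < 2L)
      counts[i, sample(n_taxa, 2L)] <- counts[i, sample(n_taxa, 2L)] + 1L
  }
  list(tree = tree, table = small_table(counts, taxa = tree$tip.label))
}

# Naive MNTD: explicit double loop over present taxa.
bf_mntd <- function(x, D, weighted) {
  p <- which(x > 0)
  nearest <- numeric(length(p))
  for (a in seq_along(p)) {
    best <- Inf
    for (b in seq_along(p)) if (a != b) best <- min(best, D[p[a], p[b]])
    nearest[a] <- best
  }
  if (weighted) sum(x[p] / sum(x[p]) * nearest) else mean(nearest)
}

# Naive betaMNTD: explicit loops, nearest neighbour in the other sample.
bf_bmntd <- function(x, y, D, weighted) {
  px <- which(x > 0); py <- which(y > 0)
  nx <- numeric(length(px)); ny <- numeric(length(py))
  for (a in seq_along(px)) {
    best <- Inf
    for (b in seq_along(py)) best <- min(best, D[px[a], py[b]])
    nx[a] <- best
  }
  for (b in seq_along(py)) {
    best <- Inf
    for (a in seq_along(px)) best <- min(best, D[py[b], px[a]])
    ny[b] <- best
  }
  if (weighted) {
    0.5 * (sum(x[px] / sum(x[px]) * nx) + sum(y[py] / sum(y[py]) * ny))
  } else 0.5 * (mean(nx) + mean(ny))
}

# Small neutral dataset for fast pipeline-level tests.
tiny_dataset <- function(seed = 5L, n_taxa = 40L, n_samples = 3L,
                         community_size = 600L) {
  cfg <- simulation_config(n_taxa = n_taxa,
                           groups = default_groups(n_samples = n_samples),
                           community_size = community_size,
                           dispersal_rate = 0.5, seed = seed)
  simulate_communities(cfg)
}
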