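#' Routine group-comparison tests
#'
#' Thin delegations to the standard implementations: Kruskal--Wallis
#' (\code{stats::kruskal.test}), Wilcoxon / Mann--Whitney rank-sum
#' (\code{stats::wilcox.test}, two-sided, tie-corrected) and two-way ANOVA
#' with interaction (\code{stats::aov}). No multiple-testing correction is
#' applied.
#'
#' @param values numeric vector, one value per sample.
#' @param labels grouping vector (for \code{two_way_anova}: a data frame
#'   or list of two factors).
#' @param test one of \code{"kruskal_wallis"}, \code{"wilcoxon"},
#'   \code{"mann_whitney"}, \code{"two_way_anova"}.
#' @return list of class \code{group_comparison}: \code{test},
#'   \code{statistic}, \code{p_value}, \code{contrast} (for two-way ANOVA,
#'   a data frame of per-term statistics instead).
#' @export
compare_groups <- function(values, labels,
                           test = c("kruskal_wallis", "wilcoxon",
                                    "mann_whitney", "two_way_anova")) {
  test <- match.arg(test)
  if (test == "two_way_anova") {
    if (!(is.list(labels) && length(labels) == 2L))
      stop("two_way_anova needs two grouping factors")
    f1 <- as.factor(labels[[1L]]); f2 <- as.factor(labels[[2L]])
    check_group_sizes(interaction(f1, f2, drop = TRUE))
    fit <- stats::aov(values ~ f1 * f2)
    tab <- summary(fit)[[1L]]
    terms <- trimws(rownames(tab))
    keep <- terms != "Residuals"
    res <- data.frame(term = c("factor1", "factor2", "interaction"),
                      F = tab$`F value`[keep], p_value = tab$`Pr(>F)`[keep],
                      stringsAsFactors = FALSE)
    return(structure(list(test = test, statistic = res$F[1L],
                          p_value = res$p_value[1L], table = res,
                          contrast = "two-way ANOVA with interaction"),
                     class = "group_comparison"))
  }
  grp <- as.factor(labels)
  check_group_sizes(grp)
  if (test == "kruskal_wallis") {
    ht <- stats::kruskal.test(values, grp)
  } else {
    if (nlevels(grp) != 2L) stop(test, " requires exactly 2 groups")
    ht <- suppressWarnings(
      stats::wilcox.test(values[grp == levels(grp)[1L]],
                         values[grp == levels(grp)[2L]], exact = FALSE))
  }
  structure(list(test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 contrast = paste(levels(grp), collapse = " vs ")),
            class = "group_comparison")
}

check_group_sizes <- function(grp) {
  sizes <- table(grp)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.4f, P = %.4g\n",
              x$test, x$contrast, x$statistic, x$p_value))
  invisible(x)
}

#' Run the full community-assembly analysis
#'
#' Orchestrates the whole study analysis per gut region: alpha diversity
#' and group tests, Bray--Curtis/Jaccard distance matrices and
#' within-group dissimilarities, PCoA, PERMANOVA/MRPP contrasts, the
#' null-model dispersion test, NTI, the betaNTI + RC five-process
#' partition, group NST, and per-group co-occurrence networks. Every
#' output is a TSV under \code{out_dir}, and a JSON manifest records every
#' seed and parameter so any stochastic stage can be reproduced exactly.
#'
#' @param table an \code{\link{otu_table}} of counts.
#' @param tree rooted \code{ape} phylo covering the table's taxa.
#' @param metadata data frame with \code{sample_id}, \code{gut_region} and
#'   \code{diet_group} columns.
#' @param out_dir output directory (created).
#' @param n_null betaNTI tip-shuffle repetitions.
#' @param rc_reps RC/NST null repetitions.
#' @param n_perm permutations for PERMANOVA/MRPP/PERMDISP.
#' @param network_threshold absolute Spearman threshold for network edges.
#' @param top_genera number of most-abundant taxa entering the networks.
#' @param seed integer master seed.
#' @return invisibly, a list of the per-region result objects.
#' @export
run_full_analysis <- function(table, tree, metadata, out_dir,
                              n_null = 999L, rc_reps = 999L,
                              n_perm = 999L, network_threshold = 0.5,
                              top_genera = 20L, seed = 1L) {
  validate_inputs(table, metadata = metadata, tree = tree)
  for (col in c("gut_region", "diet_group"))
    if (!col %in% names(metadata)) stop("metadata has no column '", col, "'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage:", name), file.path(out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  md <- metadata[match(rownames(table), metadata$sample_id), , drop = FALSE]
  results <- list()
  for (region in unique(md$gut_region)) {
    s <- rownames(table)[md$gut_region == region]
    sub <- otu_table(unclass(table)[s, , drop = FALSE])
    sub <- otu_table(unclass(sub)[, colSums(sub) > 0, drop = FALSE])
    rmd <- md[md$gut_region == region, , drop = FALSE]
    pref <- function(name) paste0(region, "_", name)

    alpha <- stage("alpha_diversity", alpha_diversity(sub, tree))
    tsv(alpha, pref("alpha.tsv"))
    atests <- stage("alpha_tests", do.call(rbind, lapply(
      c("shannon", "simpson", "faith_pd"), function(idx) {
        ct <- compare_groups(alpha[[idx]], rmd$diet_group, "kruskal_wallis")
        data.frame(index = idx, statistic = ct$statistic,
                   p_value = ct$p_value)
      })))
    tsv(atests, pref("alpha_tests.tsv"))

    betat <- list()
    for (metric in c("bray_curtis", "jaccard")) {
      dm <- stage("distance_matrix", distance_matrix(sub, metric))
      tsv(data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
          pref(paste0("dm_", metric, ".tsv")))
      wg <- within_group_dissimilarities(dm, rmd, "diet_group")
      tsv(data.frame(group = rep(names(wg), lengths(wg)),
                     dissimilarity = unlist(wg, use.names = FALSE)),
          pref(paste0("within_group_", metric, ".tsv")))
      ord <- stage("pcoa", pcoa(dm))
      tsv(data.frame(sample_id = rownames(ord$coordinates),
                     ord$coordinates[, 1:2, drop = FALSE],
                     check.names = FALSE),
          pref(paste0("pcoa_", metric, ".tsv")))
      pa <- stage("permanova",
                  permanova(dm, rmd$diet_group, n_perm, seed))
      mr <- stage("mrpp", mrpp(dm, rmd$diet_group, n_perm, seed))
      betat[[metric]] <- data.frame(
        metric = metric, delta = mr$statistic, mrpp_p = mr$p_value,
        pseudo_F = pa$statistic, permanova_p = pa$p_value)
      nd <- stage("null_dispersion",
                  null_dispersion_test(sub, metric = metric,
                                       reps = min(30L, rc_reps),
                                       n_perm = n_perm, seed = seed))
      tsv(data.frame(metric = metric,
                     actual_centroid = nd$actual_centroid,
                     null_centroid = nd$null_centroid,
                     F = nd$F, p = nd$p),
          pref(paste0("null_dispersion_", metric, ".tsv")))
    }
    tsv(do.call(rbind, betat), pref("beta_tests.tsv"))

    nti_v <- stage("nti", nti(sub, tree, n_null = n_null, seed = seed))
    tsv(data.frame(sample_id = names(nti_v), nti = unname(nti_v)),
        pref("nti.tsv"))

    fit <- stage("community_assembly",
                 community_assembly(sub, tree, rmd, group = "diet_group",
                                    n_null = n_null, rc_reps = rc_reps,
                                    seed = seed))
    tsv(data.frame(sample_id = rownames(fit$bnti), fit$bnti,
                   check.names = FALSE), pref("bnti.tsv"))
    tsv(data.frame(sample_id = rownames(fit$rc), fit$rc,
                   check.names = FALSE), pref("rc.tsv"))
    tsv(data.frame(group = rownames(fit$group_fractions),
                   fit$group_fractions, check.names = FALSE),
        pref("process_fractions.tsv"))
    tsv(fit$group_nst, pref("nst.tsv"))

    rel <- to_relative_abundance(sub)
    topg <- top_n_taxa(rel, min(top_genera, ncol(rel)))
    for (g in unique(rmd$diet_group)) {
      gs <- rmd$sample_id[rmd$diet_group == g]
      net <- stage("network",
                   spearman_network(otu_table(unclass(topg)[gs, , drop = FALSE]),
                                    threshold = network_threshold))
      write_network(net, file.path(out_dir, pref(paste0("network_", g, ".tsv"))))
      nm <- network_metrics(net)
      tsv(data.frame(group = g, as.data.frame(nm)),
          pref(paste0("network_metrics_", g, ".tsv")))
    }
    results[[region]] <- list(alpha = alpha, assembly = fit, nti = nti_v)
  }
  manifest <- list(seed = seed, n_null = n_null, rc_reps = rc_reps,
                   n_perm = n_perm, network_threshold = network_threshold,
                   top_genera = top_genera,
                   n_samples = nrow(table), n_taxa = ncol(table),
                   regions = unique(md$gut_region))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
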