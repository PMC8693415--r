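#' Fit the community-assembly null-model analysis
#'
#' The package's central estimator. For a set of samples it computes the
#' per-pair betaNTI (tip-shuffle phylogenetic null), the per-pair
#' Raup--Crick null deviation, classifies every pair into one of five
#' ecological processes (variable selection, homogeneous selection,
#' dispersal limitation, homogenizing dispersal, drift), and summarizes
#' each group by its process fractions and normalized stochasticity ratio
#' (NST, Bray--Curtis and Jaccard).
#'
#' @param table an \code{\link{otu_table}} (counts).
#' @param tree rooted \code{ape} phylo with branch lengths covering the
#'   table's taxa.
#' @param metadata data frame with \code{sample_id} and the grouping
#'   column.
#' @param group name of the metadata column defining groups
#'   (default \code{"group"}).
#' @param n_null tip-shuffle repetitions for betaNTI.
#' @param rc_reps null-community repetitions for RC and NST.
#' @param seed integer master seed; every stochastic stage derives its
#'   substream from it.
#' @param abundance_weighted use abundance-weighted betaMNTD (default).
#' @param nst_pool samples defining the NST/RC null pool: \code{"all"}
#'   (every sample in \code{table}, the default) or \code{"group"}
#'   (each group is its own pool).
#' @return object of class \code{community_assembly} with components
#'   \code{bnti} (matrix), \code{rc} (matrix), \code{partition}
#'   (overall \code{\link{partition_processes}} result),
#'   \code{group_fractions} (per-group process fractions over within-group
#'   pairs), \code{group_nst} (per-group NST, both metrics),
#'   \code{groups}, and \code{call}.
#' @seealso \code{\link{partition_processes}}, \code{\link{nst}},
#'   \code{\link{bnti_matrix}}, \code{\link{rc_matrix}}
#' @export
community_assembly <- function(table, tree, metadata, group = "group",
                               n_null = 999L, rc_reps = 999L, seed = 1L,
                               abundance_weighted = TRUE,
                               nst_pool = c("all", "group")) {
  nst_pool <- match.arg(nst_pool)
  validate_inputs(table, metadata = metadata, tree = tree)
  if (!group %in% names(metadata))
    stop("metadata has no column '", group, "'")
  ids <- rownames(table)
  grp <- metadata[[group]][match(ids, metadata$sample_id)]
  grp <- factor(grp)

  bnti <- bnti_matrix(table, tree, n_null = n_null, seed = seed,
                      abundance_weighted = abundance_weighted)
  rc <- rc_matrix(table, metric = "bray_curtis", reps = rc_reps,
                  seed = seed)
  part <- partition_processes(bnti, rc)

  group_fractions <- lapply(levels(grp), function(g) {
    s <- ids[grp == g]
    if (length(s) < 2L) return(NULL)
    partition_processes(bnti[s, s, drop = FALSE],
                        rc[s, s, drop = FALSE])$fractions
  })
  names(group_fractions) <- levels(grp)
  group_fractions <- do.call(rbind, group_fractions)

  group_nst <- do.call(rbind, lapply(levels(grp), function(g) {
    s <- ids[grp == g]
    if (length(s) < 3L) return(NULL)
    pool <- if (nst_pool == "all") ids else s
    data.frame(group = g,
               nst_bray = nst(table, s, "bray_curtis", reps = rc_reps,
                              seed = seed, pool = pool)$nst,
               nst_jaccard = nst(table, s, "jaccard", reps = rc_reps,
                                 seed = seed, pool = pool)$nst,
               n_samples = length(s), stringsAsFactors = FALSE)
  }))

  structure(list(bnti = bnti, rc = rc, partition = part,
                 group_fractions = group_fractions, group_nst = group_nst,
                 groups = stats::setNames(as.character(grp), ids),
                 n_null = n_null, rc_reps = rc_reps, seed = seed,
                 call = match.call()),
            class = "community_assembly")
}

#' @export
print.community_assembly <- function(x, ...) {
  cat("Community assembly analysis\n")
  cat("  Samples:", nrow(x$bnti), "  Groups:",
      length(unique(x$groups)), "\n")
  cat("  Null reps: betaNTI", x$n_null, "| RC/NST", x$rc_reps, "\n")
  dom <- names(which.max(x$partition$fractions))
  cat("  Dominant process:", dom,
      sprintf("(%.1f%% of pairs)\n", 100 * max(x$partition$fractions)))
  invisible(x)
}

#' Summarize a community-assembly fit
#'
#' @param object a \code{community_assembly} fit.
#' @param ... unused.
#' @return object of class \code{summary.community_assembly}.
#' @export
summary.community_assembly <- function(object, ...) {
  ut <- upper.tri(object$bnti)
  b <- object$bnti[ut]
  structure(list(fit = object,
                 mean_bnti = mean(b, na.rm = TRUE),
                 frac_stochastic_bnti = mean(abs(b) <= 2, na.rm = TRUE),
                 fractions = object$partition$fractions,
                 group_fractions = object$group_fractions,
                 group_nst = object$group_nst),
            class = "summary.community_assembly")
}

#' @export
print.summary.community_assembly <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nMean betaNTI: %.3f  (|betaNTI| <= 2 for %.1f%% of pairs)\n",
              x$mean_bnti, 100 * x$frac_stochastic_bnti))
  cat("\nProcess fractions (all pairs):\n")
  print(round(x$fractions, 3))
  if (!is.null(x$group_fractions)) {
    cat("\nWithin-group process fractions:\n")
    print(round(x$group_fractions, 3))
  }
  if (!is.null(x$group_nst)) {
    cat("\nGroup NST (%):\n")
    print(x$group_nst, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a community-assembly fit
#'
#' Two base-graphics panels: within-group betaNTI boxplots with the +/-2
#' significance band, and a stacked barplot of within-group process
#' fractions.
#'
#' @param x a \code{community_assembly} fit.
#' @param which \code{1} (betaNTI boxplot), \code{2} (process fractions),
#'   or both.
#' @param ... passed to the underlying plot calls.
#' @return invisibly, \code{x}.
#' @export
plot.community_assembly <- function(x, which = c(1L, 2L), ...) {
  if (length(which) > 1L) {
    op <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(op))
  }
  ids <- rownames(x$bnti)
  if (1L %in% which) {
    vals <- list()
    for (g in unique(x$groups)) {
      s <- ids[x$groups[ids] == g]
      if (length(s) >= 2L) {
        sub <- x$bnti[s, s, drop = FALSE]
        vals[[g]] <- sub[upper.tri(sub)]
      }
    }
    graphics::boxplot(vals, ylab = "betaNTI", las = 2, ...)
    graphics::abline(h = c(-2, 2), lty = 2, col = "grey40")
  }
  if (2L %in% which && !is.null(x$group_fractions)) {
    graphics::barplot(t(x$group_fractions), legend.text = TRUE,
                      ylab = "process fraction", las = 2,
                      args.legend = list(x = "topright", cex = 0.6), ...)
  }
  invisible(x)
}
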