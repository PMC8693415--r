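#' Shannon diversity (natural log)
#'
#' H = -sum p_i ln p_i over taxa with positive abundance; 0 for a
#' single-taxon sample. Reported in nats.
#'
#' @param counts non-negative abundance vector with at least one positive
#'   entry.
#' @return Shannon index in nats.
#' @export
shannon <- function(counts) {
  check_abundance(counts)
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Gini--Simpson diversity
#'
#' 1 - sum p_i^2: the probability that two randomly drawn individuals
#' belong to different taxa.
#'
#' @inheritParams shannon
#' @return Gini--Simpson index in [0, 1).
#' @export
simpson <- function(counts) {
  check_abundance(counts)
  unname(vegan::diversity(counts, index = "simpson"))
}

#' Faith's phylogenetic diversity (rooted)
#'
#' Sum of branch lengths of the minimal subtree connecting the present
#' taxa to the root (the path to the root is included).
#'
#' @param present character vector of present taxon ids, all tips of
#'   \code{tree}.
#' @param tree an \code{ape} phylo with branch lengths.
#' @return total branch length in the tree's units.
#' @export
faith_pd <- function(present, tree) {
  check_tree(tree)
  present <- unique(as.character(present))
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("taxa not on tree: ", paste(missing, collapse = ", "))
  if (length(present) == 0L) stop("no taxa present")
  ntip <- length(tree$tip.label)
  tips <- match(present, tree$tip.label)
  # walk each present tip to the root, marking edges on the way; PD is the
  # summed length of the marked edge set
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen[tree$edge[, 2L]] <- tree$edge.length
  on_path <- logical(ntip + tree$Nnode)
  for (tip in tips) {
    node <- tip
    while (node != 0L && !on_path[node]) {
      on_path[node] <- TRUE
      node <- parent[node]
    }
  }
  sum(elen[on_path])
}

#' Per-sample alpha diversity table
#'
#' Shannon, Gini--Simpson and (when a tree is supplied) Faith's PD for
#' every sample of an OTU table.
#'
#' @param table an \code{\link{otu_table}}.
#' @param tree optional \code{ape} phylo covering the table's taxa.
#' @return data frame with one row per sample.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  out <- data.frame(sample_id = rownames(table),
                    shannon = apply(table, 1L, shannon),
                    simpson = apply(table, 1L, simpson),
                    stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    validate_inputs(table, tree = tree)
    out$faith_pd <- apply(table, 1L, function(x)
      faith_pd(colnames(table)[x > 0], tree))
  }
  rownames(out) <- out$sample_id
  out
}

#' Bray--Curtis dissimilarity between two abundance vectors
#'
#' sum |x_i - y_i| / sum (x_i + y_i).
#'
#' @param x,y non-negative abundance vectors of equal length, not both
#'   all-zero.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  if (sum(x) + sum(y) == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / sum(x + y)
}

#' Jaccard dissimilarity (presence/absence)
#'
#' 1 - |A intersect B| / |A union B| on the positive-support sets.
#'
#' @inheritParams bray_curtis
#' @return dissimilarity in [0, 1].
#' @export
jaccard <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  a <- x > 0; b <- y > 0
  if (!any(a) && !any(b)) stop("both vectors are empty")
  1 - sum(a & b) / sum(a | b)
}

#' Pairwise sample dissimilarity matrix
#'
#' Bray--Curtis (abundance) or Jaccard (incidence) dissimilarities between
#' all sample pairs, as a symmetric matrix with zero diagonal.
#'
#' @param table an \code{\link{otu_table}} with >= 2 samples.
#' @param metric \code{"bray_curtis"} or \code{"jaccard"}.
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
distance_matrix <- function(table, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  if (nrow(table) < 2L) stop("need at least 2 samples")
  d <- if (metric == "bray_curtis")
    vegan::vegdist(unclass(table), method = "bray")
  else
    vegan::vegdist(unclass(table), method = "jaccard", binary = TRUE)
  m <- as.matrix(d)
  diag(m) <- 0
  m
}

#' Within-group pairwise dissimilarities
#'
#' For each group, the n(n-1)/2 off-diagonal dissimilarities among its
#' samples; the raw material of within-group beta-diversity boxplots.
#'
#' @param dm symmetric dissimilarity matrix with sample-id dimnames.
#' @param metadata data frame with \code{sample_id} and the grouping column.
#' @param group_field name of the grouping column.
#' @return named list, one numeric vector per group.
#' @export
within_group_dissimilarities <- function(dm, metadata, group_field) {
  check_dm(dm)
  if (!group_field %in% names(metadata))
    stop("metadata has no column '", group_field, "'")
  ids <- rownames(dm)
  grp <- metadata[[group_field]][match(ids, metadata$sample_id)]
  if (anyNA(grp)) stop("sample(s) missing from metadata: ",
                       paste(ids[is.na(grp)], collapse = ", "))
  out <- lapply(split(ids, grp), function(s) {
    if (length(s) < 2L) {
      warning("group with fewer than 2 samples; returning no pairs")
      return(numeric(0))
    }
    sub <- dm[s, s, drop = FALSE]
    sub[lower.tri(sub)]
  })
  out
}

check_abundance <- function(counts) {
  if (any(counts < 0) || anyNA(counts)) stop("abundances must be non-negative")
  if (sum(counts) == 0) stop("all-zero abundance vector")
  invisible(TRUE)
}

check_dm <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("dissimilarity matrix must be square")
  if (is.null(rownames(dm))) stop("dissimilarity matrix needs sample ids")
  if (max(abs(dm - t(dm))) > 1e-12) stop("dissimilarity matrix is not symmetric")
  if (any(diag(dm) != 0)) stop("dissimilarity matrix diagonal must be zero")
  invisible(TRUE)
}
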