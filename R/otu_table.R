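#' Construct a validated OTU table
#'
#' An OTU table is a numeric matrix of non-negative abundances with one row
#' per sample and one column per taxon, carrying unique sample and taxon
#' identifiers as dimnames. It is the universal input of every analysis in
#' the package.
#'
#' @param counts numeric matrix (samples x taxa) with dimnames, or an object
#'   coercible to one.
#' @return a matrix of class \code{otu_table}.
#' @export
otu_table <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("OTU table body must be numeric")
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("OTU table is empty")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("OTU table needs sample (row) and taxon (column) identifiers")
  dup_s <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_s))
    stop("duplicated sample identifier(s): ", paste(dup_s, collapse = ", "))
  dup_t <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_t))
    stop("duplicated taxon identifier(s): ", paste(dup_t, collapse = ", "))
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("OTU table contains missing or non-finite values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop("negative abundance for sample '", rownames(counts)[bad[1L]],
         "', taxon '", colnames(counts)[bad[2L]], "'")
  }
  class(counts) <- c("otu_table", "matrix", "array")
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x), "samples x", ncol(x), "taxa\n")
  cat("Total count:", sum(x), "\n")
  invisible(x)
}

#' Read an OTU table from a TSV file
#'
#' The file must be tab-separated with identifiers in the first row and
#' first column and a numeric body. QIIME-style exports put taxa in rows;
#' set \code{orientation} accordingly and the table is normalized to
#' samples-as-rows.
#'
#' @param path path to a TSV file.
#' @param orientation \code{"taxa_as_rows"} (the common feature-table
#'   export) or \code{"samples_as_rows"}.
#' @return an \code{\link{otu_table}} with samples as rows.
#' @export
read_otu_table <- function(path, orientation = c("taxa_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty or malformed table: ", path)
  ids <- as.character(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn))
        stop("non-numeric value in column '", names(body)[j], "', row '",
             ids[which(is.na(vn))[1L]], "'")
      body[[j]] <- vn
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "taxa_as_rows") m <- t(m)
  otu_table(m)
}

#' Write an OTU table to a TSV file
#'
#' @param table an \code{\link{otu_table}}.
#' @param path output path.
#' @param orientation row layout to write (see \code{\link{read_otu_table}}).
#' @export
write_otu_table <- function(table, path,
                            orientation = c("taxa_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  m <- unclass(table)
  id_name <- "sample_id"
  if (orientation == "taxa_as_rows") {
    m <- t(m)
    id_name <- "taxon_id"
  }
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total so rows sum to one. Compositional
#' summaries (stacked-bar figures, top-N ranking, co-occurrence networks)
#' are built on this transform.
#'
#' @param table an \code{\link{otu_table}} with positive row totals.
#' @return an \code{otu_table} of per-sample proportions.
#' @export
to_relative_abundance <- function(table) {
  totals <- rowSums(table)
  if (any(totals <= 0))
    stop("sample(s) with zero total count: ",
         paste(rownames(table)[totals <= 0], collapse = ", "))
  otu_table(unclass(table) / totals)
}

#' Aggregate an OTU table to a taxonomic rank
#'
#' Sums member-OTU counts into one column per rank label; per-sample totals
#' are conserved exactly.
#'
#' @param table an \code{\link{otu_table}}.
#' @param taxonomy data frame with a \code{taxon_id} column and one column
#'   per rank (e.g. \code{kingdom}, \code{phylum}, \code{genus}).
#' @param rank name of the taxonomy column to aggregate by.
#' @return an \code{otu_table} whose taxa are the unique rank labels.
#' @export
aggregate_by_rank <- function(table, taxonomy, rank) {
  if (!rank %in% names(taxonomy)) stop("rank '", rank, "' not in taxonomy")
  if (!"taxon_id" %in% names(taxonomy)) stop("taxonomy needs a taxon_id column")
  missing <- setdiff(colnames(table), taxonomy$taxon_id)
  if (length(missing))
    stop("taxa missing from taxonomy: ", paste(missing, collapse = ", "))
  labels <- taxonomy[[rank]][match(colnames(table), taxonomy$taxon_id)]
  if (any(!nzchar(labels)) || anyNA(labels))
    stop("empty rank label at rank '", rank, "'")
  out <- t(rowsum(t(unclass(table)), group = labels))
  otu_table(out)
}

#' Keep the most abundant taxa
#'
#' Ranks taxa by mean relative abundance across samples (the conventional
#' basis of "top N" composition figures) and keeps the top \code{n}, with a
#' deterministic lexicographic tie-break on the taxon identifier.
#'
#' @param table an \code{\link{otu_table}} of counts or proportions.
#' @param n number of taxa to keep.
#' @return an \code{otu_table} with \code{n} columns.
#' @export
top_n_taxa <- function(table, n) {
  if (n < 1L || n > ncol(table))
    stop("n must be between 1 and the number of taxa (", ncol(table), ")")
  rel <- to_relative_abundance(table)
  score <- colMeans(rel)
  ord <- order(-score, colnames(table), method = "radix")
  keep <- sort(colnames(table)[ord[seq_len(n)]])
  otu_table(unclass(table)[, keep, drop = FALSE])
}

#' Rarefy an OTU table to an even depth
#'
#' Subsamples each sample's counts without replacement to \code{depth}
#' individuals. Provided for sensitivity analysis; no analysis in the
#' package rarefies by default.
#'
#' @param table an \code{\link{otu_table}} of integer counts.
#' @param depth target library size; every sample must have at least this
#'   many individuals.
#' @param seed integer seed.
#' @return a rarefied \code{otu_table}.
#' @export
rarefy_table <- function(table, depth, seed) {
  if (any(rowSums(table) < depth))
    stop("sample(s) below rarefaction depth: ",
         paste(rownames(table)[rowSums(table) < depth], collapse = ", "))
  with_seed(seed, {
    out <- t(apply(unclass(table), 1L, function(x) {
      picks <- sample(rep.int(seq_along(x), x), depth)
      tabulate(picks, nbins = length(x))
    }))
  })
  dimnames(out) <- dimnames(table)
  otu_table(out)
}

#' Read sample metadata from a TSV file
#'
#' Expects a \code{sample_id} column plus grouping columns such as
#' \code{diet_group} and \code{gut_region}.
#'
#' @param path path to a TSV file.
#' @return a data frame with rownames set to sample ids.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md)) stop("metadata needs a sample_id column")
  dup <- unique(md$sample_id[duplicated(md$sample_id)])
  if (length(dup))
    stop("duplicated sample id(s) in metadata: ", paste(dup, collapse = ", "))
  rownames(md) <- md$sample_id
  md
}

#' Check table / tree / metadata consistency
#'
#' Fails loudly on the mismatches that silently corrupt downstream null
#' models: samples absent from metadata and taxa absent from the tree.
#'
#' @param table an \code{\link{otu_table}}.
#' @param metadata data frame with a \code{sample_id} column, or NULL.
#' @param tree an \code{ape} phylo, or NULL.
#' @return invisibly TRUE.
#' @export
validate_inputs <- function(table, metadata = NULL, tree = NULL) {
  if (!is.null(metadata)) {
    missing <- setdiff(rownames(table), metadata$sample_id)
    if (length(missing))
      stop("sample(s) missing from metadata: ", paste(missing, collapse = ", "))
  }
  if (!is.null(tree)) {
    check_tree(tree)
    missing <- setdiff(colnames(table), tree$tip.label)
    if (length(missing))
      stop("taxa missing from tree: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Prune table and tree to their shared taxa
#'
#' Phylogenetic statistics require full tip coverage and fail loudly when a
#' taxon is absent from the tree; this helper restricts both objects to the
#' intersection. It must be invoked explicitly because pruning changes null
#' distributions.
#'
#' @param table an \code{\link{otu_table}}.
#' @param tree an \code{ape} phylo.
#' @return list with elements \code{table} and \code{tree}.
#' @export
prune_to_tree <- function(table, tree) {
  shared <- intersect(colnames(table), tree$tip.label)
  if (length(shared) < 2L) stop("fewer than 2 shared taxa between table and tree")
  tree2 <- ape::keep.tip(tree, shared)
  list(table = otu_table(unclass(table)[, shared, drop = FALSE]), tree = tree2)
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("tree tip labels are not unique")
  invisible(TRUE)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-pair substream seed, symmetric in (i, j).
pair_seed <- function(seed, i, j) {
  a <- min(i, j); b <- max(i, j)
  as.integer((as.double(seed) * 48271 + a * 75361 + b * 614657) %% 2147483629)
}
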