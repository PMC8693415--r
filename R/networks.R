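#' Spearman co-occurrence network
#'
#' Pairwise Spearman rank correlations (average ranks on ties) between
#' taxa across a sample set; an edge is kept iff rho is strictly greater
#' than the threshold or strictly lower than its negative. Intended for
#' genus-level relative abundances of the most abundant taxa.
#'
#' @param table an \code{\link{otu_table}} (typically genus-level relative
#'   abundances of the top taxa).
#' @param threshold absolute-correlation threshold in (0, 1), default 0.5.
#' @param min_samples minimum number of samples required (default 4).
#' @return list of class \code{cooccurrence_network}: \code{nodes},
#'   \code{edges} (data frame a, b, rho, sign with a < b), \code{skipped}
#'   (pairs with a zero-variance member), \code{threshold}.
#' @export
spearman_network <- function(table, threshold = 0.5, min_samples = 4L) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  if (nrow(table) < min_samples)
    stop("need at least ", min_samples, " samples")
  m <- unclass(table)
  nodes <- sort(colnames(m))
  m <- m[, nodes, drop = FALSE]
  constant <- apply(m, 2L, function(v) stats::var(v) == 0)
  edges <- list(); skipped <- list()
  for (a in seq_len(ncol(m) - 1L)) for (b in (a + 1L):ncol(m)) {
    if (constant[a] || constant[b]) {
      skipped[[length(skipped) + 1L]] <- c(nodes[a], nodes[b])
      next
    }
    rho <- stats::cor(m[, a], m[, b], method = "spearman")
    if (rho > threshold || rho < -threshold)
      edges[[length(edges) + 1L]] <-
        data.frame(a = nodes[a], b = nodes[b], rho = rho,
                   sign = if (rho > 0) "+" else "-",
                   stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges)
  else data.frame(a = character(), b = character(), rho = numeric(),
                  sign = character(), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 skipped = skipped, threshold = threshold),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges (|rho| >", x$threshold, ")\n")
  invisible(x)
}

#' Summary metrics of a co-occurrence network
#'
#' Edge count, positive-edge fraction, density over unordered node pairs,
#' mean local clustering coefficient of the unsigned unweighted skeleton
#' (isolated and degree-1 nodes contribute 0), and mean weighted degree
#' (sum of |rho| over incident edges, averaged over nodes).
#'
#' @param net a \code{\link{spearman_network}} result.
#' @return named list of metrics.
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  n <- length(net$nodes)
  ne <- nrow(net$edges)
  if (ne == 0L)
    return(list(n_nodes = n, n_edges = 0L, positive_fraction = 0,
                density = 0, mean_clustering_coefficient = 0,
                mean_weighted_degree = 0))
  g <- igraph::graph_from_data_frame(net$edges[, c("a", "b")],
                                     directed = FALSE,
                                     vertices = net$nodes)
  cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  wdeg <- numeric(n); names(wdeg) <- net$nodes
  for (k in seq_len(ne)) {
    w <- abs(net$edges$rho[k])
    wdeg[net$edges$a[k]] <- wdeg[net$edges$a[k]] + w
    wdeg[net$edges$b[k]] <- wdeg[net$edges$b[k]] + w
  }
  list(n_nodes = n, n_edges = ne,
       positive_fraction = mean(net$edges$sign == "+"),
       density = ne / (n * (n - 1) / 2),
       mean_clustering_coefficient = cc,
       mean_weighted_degree = mean(wdeg))
}

#' Hub taxa of a co-occurrence network
#'
#' Taxa ranked by unsigned degree, ties broken lexicographically.
#'
#' @param net a \code{\link{spearman_network}} result.
#' @param k number of taxa to return.
#' @return data frame with \code{genus} and \code{degree}, ordered.
#' @export
hub_genera <- function(net, k = length(net$nodes)) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (k > length(net$nodes)) stop("k exceeds node count")
  deg <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    t_a <- table(net$edges$a); t_b <- table(net$edges$b)
    deg[names(t_a)] <- deg[names(t_a)] + as.integer(t_a)
    deg[names(t_b)] <- deg[names(t_b)] + as.integer(t_b)
  }
  ord <- order(-deg, names(deg), method = "radix")
  data.frame(genus = names(deg)[ord][seq_len(k)],
             degree = unname(deg[ord])[seq_len(k)],
             stringsAsFactors = FALSE)
}

#' Write a network edge list to TSV
#'
#' @param net a \code{\link{spearman_network}} result.
#' @param path output path.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
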