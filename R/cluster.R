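# Hierarchical clustering with correlation distance and aggregation of
# expression over functional categories (MapMan-style BINs as data).

#' Hierarchical cluster analysis with correlation distance
#'
#' Agglomerative clustering of rows under distance d = 1 - Pearson r
#' and average linkage (the common Cluster 3.0 configuration).
#' Zero-variance rows have no defined correlation and are filtered
#' with a warning.
#'
#' @param mat numeric matrix (>= 2 rows after filtering).
#' @param method linkage passed to \code{\link[stats]{hclust}}
#'   (default "average").
#' @return an \code{hclust} object; attribute \code{dropped} lists
#'   filtered row names.
#' @export
hca <- function(mat, method = "average") {
  v <- apply(mat, 1, stats::sd)
  dropped <- rownames(mat)[v == 0]
  if (length(dropped)) {
    warning(length(dropped), " zero-variance rows removed before HCA")
    mat <- mat[v > 0, , drop = FALSE]
  }
  if (nrow(mat) < 2) stop("need at least 2 rows with variance")
  d <- stats::as.dist(1 - stats::cor(t(mat)))
  hc <- stats::hclust(d, method = method)
  attr(hc, "dropped") <- dropped
  hc
}

#' Aggregate log2 ratios over functional categories
#'
#' Per category, the mean over member genes of
#' \code{log2(signal_t / signal_t1)} where t1 is the first column
#' (reference time point). Categories with fewer than \code{min_size}
#' measured members are dropped and reported.
#'
#' @param gm genes x time-points matrix of positive signals (first
#'   column is the reference).
#' @param gene_sets named list of gene-id vectors (term -> members).
#' @param min_size minimum measured members per reported category
#'   (default 3).
#' @return category x time-points matrix of mean log2 ratios; attribute
#'   \code{dropped} names the categories below the size threshold.
#' @export
aggregate_by_category <- function(gm, gene_sets, min_size = 3) {
  if (any(gm <= 0)) stop("signals must be positive")
  ratios <- log2(gm / gm[, 1])
  rows <- lapply(gene_sets, function(members) {
    hit <- intersect(members, rownames(gm))
    if (length(hit) < min_size) return(NULL)
    colMeans(ratios[hit, , drop = FALSE])
  })
  keep <- !vapply(rows, is.null, logical(1))
  dropped <- names(gene_sets)[!keep]
  if (!any(keep)) stop("no category reaches min_size measured genes")
  out <- do.call(rbind, rows[keep])
  rownames(out) <- names(gene_sets)[keep]
  attr(out, "dropped") <- dropped
  out
}
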