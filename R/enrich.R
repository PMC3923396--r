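# Pathway enrichment of DE genes (two-sided Fisher exact + chi-square,
# Benjamini-Hochberg FDR, dual-threshold significance) and the
# pathway-interaction network (path-net) ranked by degree.

#' Two-sided Fisher exact p-value for a 2x2 enrichment table
#'
#' With k DE genes in a term of K universe genes, n DE genes overall
#' and a universe of N, the p-value sums the hypergeometric
#' probabilities of every table with the same margins that is no more
#' probable than the observed one (the "probability mass" two-sided
#' rule, with a 1e-7 relative tolerance on the comparison).
#'
#' @param k,K,n,N the 2x2 margins.
#' @return p-value in (0, 1].
#' @export
fisher_two_sided <- function(k, K, n, N) {
  if (K > N || n > N || k > min(K, n) || k < max(0, n - (N - K)))
    stop("inconsistent 2x2 margins")
  support <- max(0, n - (N - K)):min(K, n)
  pr <- stats::dhyper(support, K, N - K, n)
  p_obs <- pr[match(k, support)]
  min(sum(pr[pr <= p_obs * (1 + 1e-7)]), 1)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p vector of p-values in [0, 1].
#' @return q-values, monotone in the ranks of \code{p}.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Pathway enrichment of a DE gene list
#'
#' One row per term that intersects the universe: the two-sided Fisher
#' exact p, a chi-square p (no continuity correction, flagged
#' unreliable when any expected count is below 5), the BH FDR over
#' Fisher p-values, and the dual-threshold significance call
#' (p < 0.05 and FDR < 0.05).
#'
#' @param de_genes character vector of DE gene ids (subset of
#'   \code{universe}).
#' @param universe background gene ids (e.g. all probe sets with at
#'   least one Present call).
#' @param gene_sets named list of member-id vectors.
#' @param p_threshold,fdr_threshold dual significance thresholds.
#' @return data.frame (term, k, K, n, N, p_fisher, p_chi2,
#'   chi2_reliable, fdr, significant) sorted by p_fisher.
#' @export
pathway_enrichment <- function(de_genes, universe, gene_sets,
                               p_threshold = 0.05,
                               fdr_threshold = 0.05) {
  if (!length(de_genes)) stop("empty DE gene list")
  if (!all(de_genes %in% universe))
    stop("de_genes must be a subset of the universe")
  de_genes <- unique(de_genes)
  universe <- unique(universe)
  n <- length(de_genes); N <- length(universe)
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(gene_sets[[term]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, de_genes))
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    exp_counts <- outer(rowSums(tab), colSums(tab)) / N
    chi_ok <- all(exp_counts >= 5)
    p_chi <- if (any(exp_counts == 0)) 1 else
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    data.frame(term = term, k = k, K = K, n = n, N = N,
               p_fisher = fisher_two_sided(k, K, n, N),
               p_chi2 = p_chi, chi2_reliable = chi_ok,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no term intersects the universe")
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_fisher)
  out$significant <- out$p_fisher < p_threshold & out$fdr < fdr_threshold
  out[order(out$p_fisher), ]
}

#' Build the pathway-interaction network (path-net)
#'
#' Induced subgraph of the curated pathway-to-pathway relations on the
#' significant terms; per node the indegree, outdegree and their sum,
#' ranked by total degree (nodes with more interacting pathways rank
#' higher).
#'
#' @param significant_terms character vector of term ids.
#' @param relations data.frame with \code{source} and \code{target}
#'   columns (directed edges).
#' @return list with \code{nodes} (term, indegree, outdegree, degree;
#'   sorted by degree descending) and \code{edges} (the retained
#'   relation rows).
#' @export
build_path_net <- function(significant_terms, relations) {
  keep <- relations$source %in% significant_terms &
    relations$target %in% significant_terms
  edges <- relations[keep, , drop = FALSE]
  indeg <- table(factor(edges$target, levels = significant_terms))
  outdeg <- table(factor(edges$source, levels = significant_terms))
  nodes <- data.frame(term = significant_terms,
                      indegree = as.integer(indeg),
                      outdegree = as.integer(outdeg),
                      stringsAsFactors = FALSE)
  nodes$degree <- nodes$indegree + nodes$outdegree
  nodes <- nodes[order(-nodes$degree, nodes$term), ]
  rownames(nodes) <- NULL
  list(nodes = nodes, edges = edges)
}
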