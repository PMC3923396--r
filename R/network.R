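# Gene-level networks: KEGG-style signal-net with weighted degree and
# indegree/outdegree ranking, Pearson co-expression edges, and k-core
# decomposition by the classic peeling algorithm.

# Relation codes treated as undirected: binding/association 'b' and
# compound 'c'; everything else (activation 'a', phosphorylation 'p',
# expression, inhibition, ...) is directed source -> target.
UNDIRECTED_RELATIONS <- c("b", "c")

# Clean an edge table: drop self-loops, collapse duplicates summing
# weights. Returns the cleaned table plus counts of what was removed.
clean_edges <- function(edges, undirected = UNDIRECTED_RELATIONS) {
  if (is.null(edges$weight)) edges$weight <- 1
  if (is.null(edges$relation)) edges$relation <- "interaction"
  loops <- edges$source == edges$target
  edges <- edges[!loops, , drop = FALSE]
  is_undir <- edges$relation %in% undirected
  # canonical order for undirected edges so duplicates collapse
  a <- ifelse(is_undir, pmin(edges$source, edges$target), edges$source)
  b <- ifelse(is_undir, pmax(edges$source, edges$target), edges$target)
  key <- paste(a, b, edges$relation, sep = "\r")
  agg <- tapply(edges$weight, key, sum)
  first <- !duplicated(key)
  out <- data.frame(source = a[first], target = b[first],
                    relation = edges$relation[first],
                    directed = !is_undir[first],
                    stringsAsFactors = FALSE)
  out$weight <- as.numeric(agg[key[first]])
  rownames(out) <- NULL
  list(edges = out, n_self_loops = sum(loops),
       n_collapsed = sum(!first))
}

#' Build the gene signal-net from typed interactions
#'
#' DE genes are translated into the interaction namespace through the
#' ortholog map (unmapped genes are dropped and reported); the network
#' is the induced subgraph of the typed interaction table on the mapped
#' genes. Degree is the sum of connection strengths over all incident
#' edges (K_i = sum of a_ui over u != i); indegree and outdegree count
#' distinct incoming/outgoing directed edges. Nodes are ranked by
#' degree descending.
#'
#' @param de_genes character vector of DE gene ids.
#' @param ortholog_map data.frame gene_id -> ortholog_id (or NULL when
#'   the interaction table already uses gene ids).
#' @param interactions data.frame with source, relation, target and
#'   optional weight columns.
#' @return list with \code{nodes} (node, gene_id, degree, indegree,
#'   outdegree; ranked by degree), \code{edges} (cleaned, induced),
#'   and \code{unmapped} (gene ids without an ortholog).
#' @export
build_signal_net <- function(de_genes, ortholog_map, interactions) {
  if (is.null(ortholog_map)) {
    mapped <- data.frame(gene_id = de_genes, node = de_genes,
                         stringsAsFactors = FALSE)
    unmapped <- character()
  } else {
    idx <- match(de_genes, ortholog_map$gene_id)
    unmapped <- de_genes[is.na(idx)]
    mapped <- data.frame(gene_id = de_genes[!is.na(idx)],
                         node = ortholog_map$ortholog_id[idx[!is.na(idx)]],
                         stringsAsFactors = FALSE)
  }
  if (!nrow(mapped)) stop("no DE gene maps into the interaction namespace")
  cl <- clean_edges(interactions)
  e <- cl$edges
  e <- e[e$source %in% mapped$node & e$target %in% mapped$node, ,
         drop = FALSE]
  nodes <- mapped$node
  wdeg <- stats::setNames(numeric(length(nodes)), nodes)
  indeg <- outdeg <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(e))) {
    s <- e$source[i]; t <- e$target[i]; w <- e$weight[i]
    wdeg[s] <- wdeg[s] + w
    wdeg[t] <- wdeg[t] + w
    if (e$directed[i]) {
      outdeg[s] <- outdeg[s] + 1L
      indeg[t] <- indeg[t] + 1L
    }
  }
  out <- data.frame(node = nodes, gene_id = mapped$gene_id,
                    degree = as.numeric(wdeg),
                    indegree = as.integer(indeg),
                    outdegree = as.integer(outdeg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), ]
  rownames(out) <- NULL
  list(nodes = out, edges = e, unmapped = unmapped,
       n_self_loops = cl$n_self_loops)
}

#' Signed co-expression edges from Pearson correlation
#'
#' For every gene pair the Pearson correlation over samples is tested
#' (t test on the correlation); an edge is kept when |r| meets the
#' threshold and the multiplicity-corrected p-value is below the
#' significance threshold. The edge sign records the direction of
#' regulation (positive or negative co-expression).
#'
#' @param expr genes x samples matrix (log2 scale recommended; at
#'   least 3 samples). Zero-variance genes are excluded.
#' @param r_threshold minimum |r| (default 0.8).
#' @param significance_threshold corrected p cutoff (default 0.05).
#' @param multiple_testing \code{\link[stats]{p.adjust}} method over
#'   all tested pairs (default "BH").
#' @return data.frame gene_a, gene_b, r, p, p_adj, sign (+1/-1); one
#'   row per unordered pair.
#' @export
coexpression_edges <- function(expr, r_threshold = 0.8,
                               significance_threshold = 0.05,
                               multiple_testing = "BH") {
  m <- ncol(expr)
  if (m < 3) stop("need at least 3 samples per gene")
  v <- apply(expr, 1, stats::sd)
  expr <- expr[v > 0, , drop = FALSE]
  n <- nrow(expr)
  if (n < 2) stop("need at least 2 genes with variance")
  r <- stats::cor(t(expr))
  ut <- upper.tri(r)
  rv <- r[ut]
  rv_c <- pmin(pmax(rv, -1 + 1e-15), 1 - 1e-15)
  tstat <- rv_c * sqrt((m - 2) / (1 - rv_c^2))
  p <- 2 * stats::pt(-abs(tstat), df = m - 2)
  p_adj <- stats::p.adjust(p, method = multiple_testing)
  idx <- which(ut, arr.ind = TRUE)
  keep <- abs(rv) >= r_threshold & p_adj < significance_threshold
  data.frame(gene_a = rownames(expr)[idx[keep, 1]],
             gene_b = rownames(expr)[idx[keep, 2]],
             r = rv[keep], p = p[keep], p_adj = p_adj[keep],
             sign = ifelse(rv[keep] >= 0, 1L, -1L),
             stringsAsFactors = FALSE)
}

#' k-core decomposition by iterative peeling
#'
#' On the simple undirected graph (direction and weights ignored),
#' nodes of minimum degree are deleted iteratively; a node's core
#' number is the largest k for which it survives into the k-core, the
#' maximal subgraph where every node keeps at least k neighbours.
#'
#' @param nodes character vector of node ids (isolated nodes allowed).
#' @param edges data.frame with the first two columns as endpoints (or
#'   columns named gene_a/gene_b or source/target).
#' @return named integer vector of core numbers.
#' @export
k_core <- function(nodes, edges) {
  ends <- edge_endpoints(edges)
  nodes <- unique(c(nodes, ends$a, ends$b))
  n <- length(nodes)
  core <- stats::setNames(integer(n), nodes)
  if (!nrow(ends$tab)) return(core)
  # simple undirected graph: drop loops and duplicate pairs
  a <- pmin(ends$a, ends$b); b <- pmax(ends$a, ends$b)
  keep <- a != b & !duplicated(paste(a, b, sep = "\r"))
  a <- a[keep]; b <- b[keep]
  adj <- split(c(b, a), c(a, b))          # neighbour lists
  deg <- stats::setNames(integer(n), nodes)
  nb_len <- lengths(adj)
  deg[names(adj)] <- nb_len
  alive <- stats::setNames(rep(TRUE, n), nodes)
  k <- 0L
  remaining <- n
  while (remaining > 0) {
    repeat {
      victims <- names(deg)[alive & deg <= k]
      if (!length(victims)) break
      for (vtm in victims) {
        alive[vtm] <- FALSE
        core[vtm] <- k
        remaining <- remaining - 1L
        for (nb in adj[[vtm]])
          if (alive[nb]) deg[nb] <- deg[nb] - 1L
      }
    }
    k <- k + 1L
  }
  core
}

edge_endpoints <- function(edges) {
  if (all(c("gene_a", "gene_b") %in% names(edges)))
    list(a = edges$gene_a, b = edges$gene_b, tab = edges)
  else if (all(c("source", "target") %in% names(edges)))
    list(a = edges$source, b = edges$target, tab = edges)
  else list(a = as.character(edges[[1]]), b = as.character(edges[[2]]),
            tab = edges)
}

#' Rank genes by core status
#'
#' Sorts nodes by core number (descending), then unweighted degree in
#' the simple graph (descending), then node id (ascending) so ties are
#' reproducible.
#'
#' @param nodes node ids.
#' @param edges edge table as in \code{\link{k_core}}.
#' @return data.frame node, core, degree, in rank order.
#' @export
rank_core_genes <- function(nodes, edges) {
  core <- k_core(nodes, edges)
  ends <- edge_endpoints(edges)
  a <- pmin(ends$a, ends$b); b <- pmax(ends$a, ends$b)
  keep <- a != b & !duplicated(paste(a, b, sep = "\r"))
  deg_tab <- table(factor(c(a[keep], b[keep]), levels = names(core)))
  out <- data.frame(node = names(core), core = as.integer(core),
                    degree = as.integer(deg_tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$core, -out$degree, out$node), ]
  rownames(out) <- NULL
  out
}
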