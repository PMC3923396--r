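# Two-sided Fisher exact test against an exhaustive hypergeometric
# oracle, BH FDR, pathway enrichment calls, and the path-net.

# Independent enumeration oracle: log-factorial hypergeometric masses
# over the full support, summing all tables no more probable than the
# observed one (same 1e-7 relative slack as the implementation).
fisher_oracle <- function(k, K, n, N) {
  lchoose2 <- function(a, b) lgamma(a + 1) - lgamma(b + 1) -
    lgamma(a - b + 1)
  support <- max(0, n - (N - K)):min(K, n)
  logp <- lchoose2(K, support) + lchoose2(N - K, n - support) -
    lchoose2(N, n)
  pr <- exp(logp)
  min(sum(pr[pr <= pr[support == k] * (1 + 1e-7)]), 1)
}

test_that("two-sided Fisher handles degenerate and proportional tables", {
  expect_equal(fisher_two_sided(5, 50, 10, 100), 1)
  expect_equal(fisher_two_sided(0, 0, 10, 100), 1)
  expect_error(fisher_two_sided(11, 10, 11, 100), "margins")
})

test_that("Fisher p equals the exhaustive hypergeometric oracle", {
  set.seed(13)
  worst <- 0
  for (i in 1:500) {
    N <- sample(10:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample_one(max(0, n - (N - K)):min(K, n))
    delta <- abs(fisher_two_sided(k, K, n, N) - fisher_oracle(k, K, n, N))
    worst <- max(worst, delta)
  }
  expect_lt(worst, 1e-12)
})

test_that("Fisher p is invariant to transposing the 2x2 table", {
  set.seed(14)
  for (i in 1:50) {
    N <- sample(20:60, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample_one(max(0, n - (N - K)):min(K, n))
    expect_equal(fisher_two_sided(k, K, n, N),
                 fisher_two_sided(k, n, K, N), tolerance = 1e-12)
  }
})

test_that("BH step-up matches its definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.05, 7)), rep(0.05, 7))
  set.seed(15)
  for (i in 1:5) {
    p <- runif(40)
    m <- length(p)
    o <- order(p)
    # definition-level oracle: step-up with cumulative minimum
    q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
    q <- numeric(m); q[o] <- pmin(q_sorted, 1)
    expect_equal(bh_fdr(p), q)
  }
  # q-values are monotone in the ranks of p
  p <- runif(30)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("planted enriched pathways are called; null terms are not", {
  cfg <- sim_config(n_genes = 800, frac_flat = 0.5, noise_sd = 0.2,
                    planted_profiles = planted_four(100, 2),
                    n_pathways = 20, n_enriched_pathways = 3,
                    enrichment_odds = 8, seed = 61)
  e <- generate_expression(cfg)
  ann <- generate_annotations(cfg, e$truth)
  de <- e$truth$gene_id[e$truth$class == "profile"]
  tab <- pathway_enrichment(de, e$truth$gene_id, ann$gene_sets)
  enriched <- sprintf("PW%03d", 1:3)
  expect_true(all(tab$significant[tab$term %in% enriched]))
  # chi-square agrees in direction with Fisher on reliable tables
  rel <- tab$chi2_reliable
  expect_gt(stats::cor(log(tab$p_fisher[rel]), log(tab$p_chi2[rel])),
            0.9)
})

test_that("DE list equal to the universe gives p = 1 everywhere", {
  genes <- sprintf("g%03d", 1:100)
  sets <- list(A = genes[1:30], B = genes[40:60])
  tab <- pathway_enrichment(genes, genes, sets)
  expect_equal(tab$p_fisher, c(1, 1))
  expect_error(pathway_enrichment(character(), genes, sets), "empty")
  expect_error(pathway_enrichment("nope", genes, sets), "subset")
})

test_that("null enrichment p-values are not anti-conservative", {
  # odds ratio 1 everywhere: the significant fraction stays near alpha
  cfg <- sim_config(n_genes = 1000, frac_flat = 0.7, noise_sd = 0.2,
                    planted_profiles = planted_four(75, 2),
                    n_pathways = 200, n_enriched_pathways = 0,
                    pathway_size = 40, seed = 62)
  e <- generate_expression(cfg)
  ann <- generate_annotations(cfg, e$truth)
  de <- e$truth$gene_id[e$truth$class == "profile"]
  tab <- pathway_enrichment(de, e$truth$gene_id, ann$gene_sets)
  expect_lte(mean(tab$p_fisher < 0.05), 0.10)
})

test_that("path-net degrees count pathway interactions", {
  rel <- data.frame(source = c("A", "B", "A"),
                    relation = "maplink",
                    target = c("B", "C", "C"),
                    stringsAsFactors = FALSE)
  pn <- build_path_net(c("A", "B", "C"), rel)
  deg <- stats::setNames(pn$nodes$degree, pn$nodes$term)
  expect_equal(unname(deg[c("A", "B", "C")]), c(2, 2, 2))
  expect_equal(pn$nodes$indegree[pn$nodes$term == "C"], 2)
  # sum indegree = sum outdegree = retained edges
  expect_equal(sum(pn$nodes$indegree), nrow(pn$edges))
  expect_equal(sum(pn$nodes$outdegree), nrow(pn$edges))
  # terms outside the significant set are excluded
  pn2 <- build_path_net(c("A", "B"), rel)
  expect_equal(nrow(pn2$edges), 1)
  # empty relations: all degrees zero
  pn3 <- build_path_net(c("A", "B"),
                        rel[rel$source == "none", , drop = FALSE])
  expect_true(all(pn3$nodes$degree == 0))
})

test_that("path-net degrees equal an adjacency-sum oracle", {
  set.seed(16)
  terms <- sprintf("T%02d", 1:12)
  for (rep_i in 1:5) {
    rel <- data.frame(source = sample(terms, 30, replace = TRUE),
                      relation = "maplink",
                      target = sample(terms, 30, replace = TRUE),
                      stringsAsFactors = FALSE)
    keep_terms <- sample(terms, 8)
    pn <- build_path_net(keep_terms, rel)
    adj <- matrix(0, 8, 8, dimnames = list(keep_terms, keep_terms))
    for (r in seq_len(nrow(rel)))
      if (rel$source[r] %in% keep_terms && rel$target[r] %in% keep_terms)
        adj[rel$source[r], rel$target[r]] <-
          adj[rel$source[r], rel$target[r]] + 1
    for (t in keep_terms) {
      row <- pn$nodes[pn$nodes$term == t, ]
      expect_equal(row$outdegree, sum(adj[t, ]))
      expect_equal(row$indegree, sum(adj[, t]))
      expect_equal(row$degree, sum(adj[t, ]) + sum(adj[, t]))
    }
  }
})
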