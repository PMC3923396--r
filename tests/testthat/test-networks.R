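# Signal-net degrees, co-expression edges against a definition-level
# oracle, and k-core decomposition with brute-force and igraph
# cross-checks.

test_that("signal-net computes star and single-edge degrees", {
  star <- data.frame(source = rep("X", 5), relation = "b",
                     target = paste0("L", 1:5),
                     stringsAsFactors = FALSE)
  net <- build_signal_net(c("X", paste0("L", 1:5)), NULL, star)
  expect_equal(net$nodes$degree[net$nodes$node == "X"], 5)
  expect_equal(net$nodes$node[1], "X")      # ranked first by degree
  one <- data.frame(source = "A", relation = "a", target = "B",
                    stringsAsFactors = FALSE)
  net1 <- build_signal_net(c("A", "B"), NULL, one)
  a <- net1$nodes[net1$nodes$node == "A", ]
  b <- net1$nodes[net1$nodes$node == "B", ]
  expect_equal(c(a$outdegree, a$indegree, a$degree), c(1, 0, 1))
  expect_equal(c(b$outdegree, b$indegree, b$degree), c(0, 1, 1))
})

test_that("signal-net degrees equal the weighted adjacency oracle", {
  set.seed(21)
  genes <- sprintf("g%02d", 1:15)
  for (rep_i in 1:5) {
    edges <- data.frame(
      source = sample(genes, 40, replace = TRUE),
      relation = sample(c("a", "p"), 40, replace = TRUE),
      target = sample(genes, 40, replace = TRUE),
      weight = round(runif(40, 0.5, 3), 2),
      stringsAsFactors = FALSE)
    net <- build_signal_net(genes, NULL, edges)
    # oracle: weighted adjacency row+column sums on the cleaned edges
    e <- net$edges
    adj <- matrix(0, 15, 15, dimnames = list(genes, genes))
    for (r in seq_len(nrow(e)))
      adj[e$source[r], e$target[r]] <- adj[e$source[r], e$target[r]] +
        e$weight[r]
    for (g in genes) {
      row <- net$nodes[net$nodes$node == g, ]
      expect_equal(row$degree, sum(adj[g, ]) + sum(adj[, g]))
    }
    expect_equal(sum(net$nodes$indegree), sum(net$nodes$outdegree))
    expect_equal(sum(net$nodes$indegree), sum(e$directed))
  }
})

test_that("signal-net maps DE genes and reports unmapped ones", {
  omap <- data.frame(gene_id = c("G1", "G2"),
                     ortholog_id = c("K1", "K2"),
                     stringsAsFactors = FALSE)
  edges <- data.frame(source = "K1", relation = "b", target = "K2",
                      stringsAsFactors = FALSE)
  net <- build_signal_net(c("G1", "G2", "G3"), omap, edges)
  expect_equal(net$unmapped, "G3")
  expect_equal(nrow(net$edges), 1)
  expect_error(build_signal_net("G9", omap, edges), "no DE gene maps")
})

test_that("duplicate and self-loop interactions are cleaned", {
  edges <- data.frame(
    source = c("A", "B", "A", "C"),
    relation = c("b", "b", "b", "a"),
    target = c("B", "A", "A", "C"),
    stringsAsFactors = FALSE)
  net <- build_signal_net(c("A", "B", "C"), NULL, edges)
  # the two b edges collapse (undirected), self-loops drop
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 2)
  expect_equal(net$n_self_loops, 2)
})

test_that("co-expression edges match a definition-level oracle", {
  set.seed(22)
  x <- matrix(rnorm(50 * 15), 50, 15,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  # plant a few strong pairs
  x[2, ] <- x[1, ] + rnorm(15, 0, 0.1)
  x[4, ] <- -x[3, ] + rnorm(15, 0, 0.1)
  edges <- coexpression_edges(x, r_threshold = 0.8,
                              significance_threshold = 0.05)
  # oracle: explicit covariance formula + t test + BH over all pairs
  n <- nrow(x); m <- ncol(x)
  pairs <- t(utils::combn(n, 2))
  r_o <- p_o <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r_o[i] <- cor_oracle(x[pairs[i, 1], ], x[pairs[i, 2], ])
    tt <- r_o[i] * sqrt((m - 2) / (1 - r_o[i]^2))
    p_o[i] <- 2 * (1 - stats::pt(abs(tt), m - 2))
  }
  q_o <- stats::p.adjust(p_o, "BH")
  keep <- abs(r_o) >= 0.8 & q_o < 0.05
  got <- paste(edges$gene_a, edges$gene_b)
  want <- paste(rownames(x)[pairs[keep, 1]], rownames(x)[pairs[keep, 2]])
  expect_setequal(got, want)
  expect_true(all(c("g01 g02", "g03 g04") %in% got))
  expect_equal(edges$sign[edges$gene_a == "g01" & edges$gene_b == "g02"],
               1L)
  expect_equal(edges$sign[edges$gene_a == "g03" & edges$gene_b == "g04"],
               -1L)
  expect_error(coexpression_edges(x[, 1:2]), "3 samples")
})

test_that("identical and negated series give unit correlations", {
  x <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
             c = -c(1, 2, 3, 4, 5))
  e <- coexpression_edges(x, r_threshold = 0.9,
                          significance_threshold = 0.05)
  ab <- e[e$gene_a == "a" & e$gene_b == "b", ]
  ac <- e[e$gene_a == "a" & e$gene_b == "c", ]
  expect_equal(ab$r, 1)
  expect_equal(ab$sign, 1L)
  expect_equal(ac$r, -1)
  expect_equal(ac$sign, -1L)
})

test_that("k-core peels the classic examples", {
  tri <- data.frame(source = c("a", "b", "c", "c"),
                    target = c("b", "c", "a", "d"),
                    stringsAsFactors = FALSE)
  core <- k_core(c("a", "b", "c", "d"), tri)
  expect_equal(unname(core[c("a", "b", "c", "d")]), c(2, 2, 2, 1))
  cyc <- data.frame(source = letters[1:6],
                    target = letters[c(2:6, 1)],
                    stringsAsFactors = FALSE)
  expect_true(all(k_core(letters[1:6], cyc) == 2))
  # isolated node has core 0
  expect_equal(unname(k_core(c("a", "b", "z"), tri)["z"]), 0L)
})

test_that("k-core equals brute-force peeling and igraph on random graphs", {
  for (s in 1:10) {
    g <- random_graph(30, 0.2, seed = 100 + s)
    nodes <- sprintf("n%02d", 1:30)
    core <- k_core(nodes, g)
    oracle <- k_core_oracle(nodes, g)
    expect_equal(core[nodes], oracle[nodes])
    if (requireNamespace("igraph", quietly = TRUE)) {
      ig <- igraph::graph_from_data_frame(g, directed = FALSE,
                                          vertices = nodes)
      expect_equal(unname(core[nodes]),
                   unname(igraph::coreness(ig)[nodes]))
    }
  }
})

test_that("k-core is invariant to relabeling and edge order", {
  g <- random_graph(20, 0.25, seed = 31)
  nodes <- sprintf("n%02d", 1:20)
  core1 <- k_core(nodes, g)
  g2 <- g[sample(nrow(g)), ]
  core2 <- k_core(sample(nodes), g2)
  expect_equal(core1[nodes], core2[nodes])
  # relabel
  relab <- stats::setNames(sprintf("m%02d", 1:20), nodes)
  g3 <- data.frame(source = unname(relab[g$source]),
                   target = unname(relab[g$target]),
                   stringsAsFactors = FALSE)
  core3 <- k_core(unname(relab[nodes]), g3)
  expect_equal(unname(core3[unname(relab[nodes])]),
               unname(core1[nodes]))
})

test_that("core numbers are nested", {
  for (s in 1:5) {
    g <- random_graph(25, 0.25, seed = 200 + s)
    core <- k_core(sprintf("n%02d", 1:25), g)
    for (k in 1:max(core))
      expect_true(all(names(core)[core >= k + 1] %in%
                        names(core)[core >= k]))
  }
})

test_that("degree conservation holds on the simple graph", {
  g <- random_graph(20, 0.3, seed = 41)
  nodes <- sprintf("n%02d", 1:20)
  rk <- rank_core_genes(nodes, g)
  expect_equal(sum(rk$degree), 2 * nrow(g))
})

test_that("core ranking puts the clique first and breaks ties stably", {
  clique <- t(utils::combn(c("q1", "q2", "q3", "q4"), 2))
  chain <- cbind(c("c1", "c2"), c("c2", "c3"))
  g <- data.frame(source = c(clique[, 1], chain[, 1]),
                  target = c(clique[, 2], chain[, 2]),
                  stringsAsFactors = FALSE)
  rk <- rank_core_genes(c(paste0("q", 1:4), paste0("c", 1:3)), g)
  expect_setequal(rk$node[1:4], paste0("q", 1:4))
  # equal cores order by degree, then id
  expect_equal(rk$node[5], "c2")            # degree 2 beats 1
  expect_equal(rk$node[6:7], c("c1", "c3")) # id ascending
})

test_that("a planted dense module dominates the top core", {
  cfg <- sim_config(n_genes = 300, frac_flat = 0.9, noise_sd = 0.2,
                    n_coexp_modules = 2, module_size = 15, seed = 9)
  e <- generate_expression(cfg)
  edges <- coexpression_edges(log2(e$signal))
  rk <- rank_core_genes(rownames(e$signal), edges)
  top <- rk$node[rk$core == max(rk$core)]
  members <- e$truth$gene_id[!is.na(e$truth$module_id)]
  expect_gte(mean(members %in% top), 0.9)
})
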