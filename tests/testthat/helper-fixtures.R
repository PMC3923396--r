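# Shared fixture builders for the test suite. Everything is generated
# in code under fixed seeds; no binary fixtures.

# The four planted temporal shapes used across DE / STC tests:
# monotone up, monotone down, up-then-down, down-then-up.
planted_four <- function(n_per, amplitude) {
  list(list(transitions = c(1, 1, 1, 1), n_genes = n_per,
            amplitude = amplitude),
       list(transitions = c(-1, -1, -1, -1), n_genes = n_per,
            amplitude = amplitude),
       list(transitions = c(1, 1, -1, -1), n_genes = n_per,
            amplitude = amplitude),
       list(transitions = c(-1, -1, 1, 1), n_genes = n_per,
            amplitude = amplitude))
}

# A small all-null dataset.
null_dataset <- function(n_genes, noise_sd = 0.2, seed = 1) {
  cfg <- sim_config(n_genes = n_genes, frac_flat = 1,
                    noise_sd = noise_sd, seed = seed)
  generate_expression(cfg)
}

# Dataset with planted DE genes among flat ones.
planted_dataset <- function(n_genes, n_de, amplitude = 2,
                            noise_sd = 0.2, seed = 1) {
  per <- n_de %/% 2
  planted <- list(
    list(transitions = c(1, 1, 1, 1), n_genes = per,
         amplitude = amplitude),
    list(transitions = c(-1, -1, -1, -1), n_genes = n_de - per,
         amplitude = amplitude))
  cfg <- sim_config(n_genes = n_genes,
                    frac_flat = (n_genes - n_de) / n_genes,
                    planted_profiles = planted, noise_sd = noise_sd,
                    seed = seed)
  generate_expression(cfg)
}

# Definition-level Pearson correlation, written out longhand so it is
# independent of stats::cor.
cor_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Random simple undirected graph as an edge data.frame.
random_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(source = pairs[keep, 1], target = pairs[keep, 2],
             stringsAsFactors = FALSE)
}

# Brute-force k-core oracle: the k-core is what survives repeated
# deletion of nodes with degree < k; a node's core number is the
# largest k whose core still contains it.
k_core_oracle <- function(nodes, edges) {
  deg_of <- function(alive, a, b) {
    keep <- a %in% alive & b %in% alive
    tab <- table(factor(c(a[keep], b[keep]), levels = alive))
    as.integer(tab)
  }
  a <- edges$source; b <- edges$target
  core <- stats::setNames(integer(length(nodes)), nodes)
  k <- 1L
  repeat {
    alive <- nodes
    repeat {
      d <- deg_of(alive, a, b)
      drop <- alive[d < k]
      if (!length(drop)) break
      alive <- setdiff(alive, drop)
    }
    if (!length(alive)) break
    core[alive] <- k
    k <- k + 1L
  }
  core
}

# Exhaustive hypergeometric two-sided oracle via log factorials.
fisher_oracle_acc <- function(k, K, n, N) {
  lch <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)
  support <- max(0, n - (N - K)):min(K, n)
  pr <- exp(lch(K, support) + lch(N - K, n - support) - lch(N, n))
  min(sum(pr[pr <= pr[support == k] * (1 + 1e-7)]), 1)
}

# O(n^3) textbook average-linkage oracle; returns sorted merge heights.
avg_linkage_oracle_acc <- function(d) {
  active <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i >= j) next
      dd <- mean(d[active[[i]], active[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    active <- c(active[-best], list(c(active[[best[1]]],
                                      active[[best[2]]])))
  }
  sort(heights)
}

# sample one element from a vector (safe when length(x) == 1)
sample_one <- function(x) x[sample.int(length(x), 1)]
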