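# Random variance model (RVM) moderated one-way ANOVA across time
# points, permutation-based FDR and dual-threshold gene selection.
#
# Model: reciprocal gene variances are gamma-distributed, so the
# observed residual variance satisfies s^2 * a * b ~ F(df, 2a). The
# moderated residual variance shrinks each gene's s^2 toward the prior,
# inflating the denominator degrees of freedom of the ANOVA F test.

# Vectorized one-way ANOVA pieces on the log2 scale.
# Returns per-gene between-group mean square, within-group variance and
# the degrees of freedom (k - 1, N - k).
anova_components <- function(log2x, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  N <- ncol(log2x)
  if (k < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 replicates")
  G <- stats::model.matrix(~ 0 + groups)        # N x k indicator
  n_j <- colSums(G)
  sum_j <- log2x %*% G                          # genes x k group sums
  mean_j <- sweep(sum_j, 2, n_j, "/")
  grand <- rowSums(log2x) / N
  ssb <- as.vector(sweep(mean_j, 1, grand, "-")^2 %*% n_j)
  sst <- rowSums(sweep(log2x, 1, grand, "-")^2)
  ssw <- pmax(sst - ssb, 0)
  list(msb = ssb / (k - 1), s2 = ssw / (N - k),
       df1 = k - 1L, df2 = N - as.integer(k),
       group_means = mean_j, group_levels = levels(groups))
}

#' Fit RVM hyperparameters to residual variances
#'
#' Maximizes the likelihood of the observed residual variances under
#' the scaled-F model \code{s2 * a * b ~ F(df, 2a)} by numerical
#' optimization on the log scale, started from a moment-based guess.
#'
#' @param s2 per-gene residual variances (>= 100 genes).
#' @param df residual degrees of freedom (N - k).
#' @return list with \code{a}, \code{b} and the achieved log-likelihood.
#' @export
fit_rvm_hyperparams <- function(s2, df) {
  if (length(s2) < 100) stop("need >= 100 genes to fit RVM hyperparameters")
  if (df < 1) stop("residual df must be >= 1")
  s2 <- s2[s2 > 0 & is.finite(s2)]
  if (stats::sd(s2) == 0)
    stop("degenerate input: all residual variances identical; ",
         "RVM hyperparameters are unidentifiable")
  negll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(stats::df(s2 * a * b, df1 = df, df2 = 2 * a, log = TRUE) +
           log(a * b))
  }
  # moment start: if x = s2*a*b ~ F(df, 2a), E[x] = a/(a-1); match the
  # coefficient of variation of s2 to pick a, then b from the mean.
  m <- mean(s2)
  a0 <- 3
  b0 <- max((a0 / (a0 - 1)) / (m * a0), 1e-8)
  fit <- stats::optim(c(log(a0), log(b0)), negll, method = "L-BFGS-B",
                      lower = log(c(1e-2, 1e-10)),
                      upper = log(c(1e6, 1e10)))
  list(a = exp(fit$par[1]), b = exp(fit$par[2]), loglik = -fit$value)
}

#' RVM-moderated one-way ANOVA F test
#'
#' Per gene, the moderated residual variance is
#' \code{(df * s2 + 2/b) / (df + 2a)} and the moderated statistic
#' \code{F* = MSB / s2_tilde} is referred to \code{F(k - 1, df + 2a)}.
#' Genes with zero between-group variation get F* = 0 and p = 1.
#'
#' @param expr positive signal matrix (genes x samples) or log2 matrix
#'   when \code{log2_input = TRUE}.
#' @param design data.frame with \code{sample_id} and \code{time_hai}
#'   matching the columns of \code{expr}.
#' @param hyper result of \code{\link{fit_rvm_hyperparams}}; fitted on
#'   the fly when NULL.
#' @param log2_input is \code{expr} already on the log2 scale?
#' @return data.frame per gene with f_stat, p, plus attributes
#'   \code{hyper} and \code{components}.
#' @export
rvm_f_test <- function(expr, design, hyper = NULL, log2_input = FALSE) {
  if (!all(design$sample_id %in% colnames(expr)))
    stop("design samples missing from expression matrix")
  x <- expr[, design$sample_id, drop = FALSE]
  log2x <- if (log2_input) x else log2(x)
  comp <- anova_components(log2x, design$time_hai)
  if (is.null(hyper))
    hyper <- fit_rvm_hyperparams(comp$s2, comp$df2)
  s2_tilde <- (comp$df2 * comp$s2 + 2 / hyper$b) / (comp$df2 + 2 * hyper$a)
  f_stat <- comp$msb / s2_tilde
  f_stat[comp$msb == 0] <- 0
  p <- stats::pf(f_stat, comp$df1, comp$df2 + 2 * hyper$a,
                 lower.tail = FALSE)
  p[f_stat == 0] <- 1
  res <- data.frame(gene_id = rownames(log2x), f_stat = f_stat, p = p,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "hyper") <- hyper
  attr(res, "components") <- comp
  res
}

# F* statistics only, for permutation reuse (shared hyperparameters).
rvm_f_stats <- function(log2x, groups, hyper) {
  comp <- anova_components(log2x, groups)
  s2_tilde <- (comp$df2 * comp$s2 + 2 / hyper$b) / (comp$df2 + 2 * hyper$a)
  f <- comp$msb / s2_tilde
  f[comp$msb == 0] <- 0
  f
}

#' Permutation-based FDR for the moderated F statistics
#'
#' Array labels are permuted freely across groups (a global-null
#' permutation); at each observed statistic t the FDR is the mean
#' permuted count of statistics >= t divided by the observed count,
#' clipped to [0, 1] and made monotone non-increasing in t by a
#' cumulative minimum from the largest statistic downward.
#'
#' @param de_result result of \code{\link{rvm_f_test}} (carries the
#'   fitted hyperparameters).
#' @param expr,design,log2_input as in \code{\link{rvm_f_test}}.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for the permutation draws.
#' @param force run even when \code{n_perm < 100}.
#' @return the input data.frame with an \code{fdr} column added.
#' @export
permutation_fdr <- function(de_result, expr, design, n_perm = 1000,
                            seed = 1, log2_input = FALSE, force = FALSE) {
  if (n_perm < 100 && !force)
    stop("n_perm < 100 gives unstable FDR estimates; use force = TRUE ",
         "to override")
  hyper <- attr(de_result, "hyper")
  if (is.null(hyper)) stop("de_result lacks fitted hyperparameters")
  x <- expr[, design$sample_id, drop = FALSE]
  log2x <- if (log2_input) x else log2(x)
  f_obs <- de_result$f_stat
  ord <- order(f_obs, decreasing = TRUE)
  f_sorted <- f_obs[ord]
  # inclusive ">= t" counts on both sides; ties share the full count
  obs_sorted_asc <- sort(f_obs)
  n_ge_obs <- length(f_obs) -
    findInterval(f_sorted - 1e-12, obs_sorted_asc)

  set.seed(seed)
  groups <- design$time_hai
  perm_all <- matrix(NA_real_, nrow(log2x), n_perm)
  for (i in seq_len(n_perm))
    perm_all[, i] <- rvm_f_stats(log2x, sample(groups), hyper)
  perm_sorted <- sort(as.vector(perm_all))
  # mean permuted count >= t, via binary search on the sorted pool
  n_ge_perm <- (length(perm_all) -
                  findInterval(f_sorted - 1e-12, perm_sorted)) / n_perm
  fdr_sorted <- pmin(pmax(n_ge_perm / n_ge_obs, 0), 1)
  # monotone enforcement: scanning thresholds from the largest observed
  # statistic downward, each gene takes the smallest ratio achievable at
  # any weaker threshold, so FDR is non-increasing in F
  fdr_sorted <- rev(cummin(rev(fdr_sorted)))
  fdr <- numeric(length(f_obs))
  fdr[ord] <- fdr_sorted
  de_result$fdr <- fdr
  de_result
}

#' Per-time-point geometric means of the signal
#'
#' The per-group expression value is the geometric mean of the
#' replicate signals (equivalently the arithmetic mean of log2 values),
#' the summary used for fold changes and up/down direction.
#'
#' @param expr positive signal matrix (genes x samples).
#' @param design design table.
#' @return genes x time-points matrix of geometric-mean signals, with
#'   time points as ordered columns.
#' @export
timepoint_means <- function(expr, design) {
  x <- log2(expr[, design$sample_id, drop = FALSE])
  tps <- sort(unique(design$time_hai))
  out <- vapply(tps, function(t)
    rowMeans(x[, design$time_hai == t, drop = FALSE]),
    numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x),
                dimnames = list(rownames(x), as.character(tps)))
  2^out
}

#' Select differentially expressed genes and count up/down transitions
#'
#' A gene is declared DE when p < \code{p_threshold} and FDR <
#' \code{fdr_threshold}; among DE genes, each successive time-point
#' pair is classified up or down by the direction of the change in
#' geometric-mean signal (no call when the means are equal).
#'
#' @param de_result data.frame from \code{\link{permutation_fdr}} (must
#'   carry \code{p} and \code{fdr}).
#' @param expr,design as in \code{\link{rvm_f_test}}.
#' @param p_threshold,fdr_threshold dual selection thresholds
#'   (defaults 0.05 / 0.05).
#' @return list with \code{de_genes}, the augmented \code{table}
#'   (is_de flag), \code{updown} (per-pair up/down counts) and
#'   \code{direction} (DE genes x pairs matrix of -1/0/+1).
#' @export
select_de <- function(de_result, expr, design, p_threshold = 0.05,
                      fdr_threshold = 0.05) {
  if (is.null(de_result$fdr)) stop("run permutation_fdr first")
  is_de <- de_result$p < p_threshold & de_result$fdr < fdr_threshold
  de_result$is_de <- is_de
  gm <- timepoint_means(expr, design)
  gm <- gm[de_result$gene_id, , drop = FALSE]
  tps <- colnames(gm)
  n_pair <- ncol(gm) - 1L
  dir_mat <- matrix(0L, sum(is_de), n_pair,
                    dimnames = list(de_result$gene_id[is_de], NULL))
  updown <- data.frame(from = tps[-length(tps)], to = tps[-1],
                       up = 0L, down = 0L, stringsAsFactors = FALSE)
  if (any(is_de)) {
    d <- gm[is_de, -1, drop = FALSE] - gm[is_de, -ncol(gm), drop = FALSE]
    dir_mat <- sign(d)
    updown$up <- colSums(dir_mat > 0)
    updown$down <- colSums(dir_mat < 0)
  }
  list(de_genes = de_result$gene_id[is_de], table = de_result,
       updown = updown, direction = dir_mat)
}
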