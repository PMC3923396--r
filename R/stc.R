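# Series Test of Cluster (STC): a data-independent catalogue of
# discretized temporal model profiles; genes are assigned by Pearson
# correlation and profile over-representation is tested against a
# time-point permutation null, then significant profiles are grouped
# by similarity.

# Encode a transition vector (values in -c..c) as a base-(2c+1) id,
# first interval most significant digit.
profile_id_from_transitions <- function(transitions, c = max(abs(transitions), 1)) {
  digits <- transitions + c
  base <- 2 * c + 1
  sum(digits * base^((length(digits) - 1):0))
}

#' Enumerate model temporal profiles
#'
#' All \code{(2c+1)^(T-1)} profiles of per-interval steps in
#' \code{-c..c}. A profile's sequence is the cumulative sum of its
#' transitions, starting at 0; its id is the base-(2c+1) encoding of
#' the shifted transitions with the first interval as the most
#' significant digit (the flat profile therefore sits in the middle of
#' the id range). When the full set exceeds \code{max_profiles}, a
#' representative subset is chosen by greedy max-min distance with
#' d = 1 - Pearson r.
#'
#' @param T number of time points (>= 2).
#' @param c maximum per-interval step (>= 1).
#' @param max_profiles optional cap triggering representative-subset
#'   selection (default Inf: keep all).
#' @return data.frame with \code{profile_id} and a \code{sequence}
#'   matrix column-bound as \code{seq_1..seq_T}; attribute
#'   \code{transitions} holds the step matrix.
#' @examples
#' p <- enumerate_profiles(5, 1)  # 81 profiles, ids 0..80
#' @export
enumerate_profiles <- function(T, c = 1, max_profiles = Inf) {
  stopifnot(T >= 2)
  if (c < 1) stop("c must be >= 1 (c = 0 leaves only the flat profile)")
  steps <- seq(-c, c)
  grid <- as.matrix(expand.grid(rep(list(steps), T - 1)))[, (T - 1):1,
                                                          drop = FALSE]
  colnames(grid) <- NULL
  ids <- apply(grid, 1, profile_id_from_transitions, c = c)
  ord <- order(ids)
  grid <- grid[ord, , drop = FALSE]
  ids <- ids[ord]
  cs <- apply(grid, 1, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
  seqs <- cbind(0, t(cs))
  colnames(seqs) <- paste0("seq_", seq_len(T))
  out <- data.frame(profile_id = ids)
  out <- cbind(out, as.data.frame(seqs))
  attr(out, "transitions") <- grid
  attr(out, "c") <- c
  if (is.finite(max_profiles) && nrow(out) > max_profiles)
    out <- representative_profiles(out, max_profiles)
  out
}

# Greedy max-min selection of a representative profile subset under
# d = 1 - Pearson r between sequences; the flat profile is kept.
representative_profiles <- function(profiles, m) {
  seqs <- profile_sequences(profiles)
  v <- apply(seqs, 1, stats::sd)
  keep_flat <- which(v == 0)
  cand <- which(v > 0)
  r <- suppressWarnings(stats::cor(t(seqs[cand, , drop = FALSE])))
  d <- 1 - r
  chosen <- cand[1]
  while (length(chosen) < m - length(keep_flat)) {
    ci <- match(chosen, cand)
    mind <- apply(d[, ci, drop = FALSE], 1, min)
    mind[ci] <- -Inf
    chosen <- c(chosen, cand[which.max(mind)])
  }
  sel <- sort(c(keep_flat, chosen))
  out <- profiles[sel, , drop = FALSE]
  attr(out, "transitions") <- attr(profiles, "transitions")[sel, ,
                                                            drop = FALSE]
  attr(out, "c") <- attr(profiles, "c")
  out
}

profile_sequences <- function(profiles) {
  as.matrix(profiles[, grep("^seq_", names(profiles)), drop = FALSE])
}

#' Assign genes to model profiles by correlation
#'
#' Each gene's per-time series (log2, referenced to the first time
#' point internally) is assigned to the non-flat model profile with the
#' highest Pearson correlation; ties break to the lowest profile id.
#' Zero-variance genes cannot be correlated and are excluded and
#' reported. The flat profile is excluded from the argmax since
#' correlation with a constant sequence is undefined.
#'
#' @param series genes x T matrix of log2 per-time-point summaries
#'   (absolute values are fine; each row is re-referenced to its first
#'   entry).
#' @param profiles from \code{\link{enumerate_profiles}}.
#' @return list with \code{assignment} (data.frame gene_id, profile_id,
#'   correlation), \code{counts} (named per-profile counts including
#'   zeros), and \code{excluded} (data.frame gene_id, reason).
#' @export
assign_genes <- function(series, profiles) {
  seqs <- profile_sequences(profiles)
  if (ncol(series) != ncol(seqs))
    stop("series and profiles disagree on the number of time points")
  rel <- series - series[, 1]
  v <- apply(rel, 1, stats::sd)
  ok <- which(v > 0)
  excluded <- data.frame(gene_id = rownames(series)[v == 0],
                         reason = rep("zero variance", sum(v == 0)),
                         stringsAsFactors = FALSE)
  pv <- apply(seqs, 1, stats::sd)
  nonflat <- which(pv > 0)
  if (!length(ok)) {
    counts <- stats::setNames(integer(nrow(profiles)),
                              profiles$profile_id)
    return(list(assignment = data.frame(gene_id = character(),
                                        profile_id = integer(),
                                        correlation = numeric(),
                                        stringsAsFactors = FALSE),
                counts = counts, excluded = excluded))
  }
  r <- suppressWarnings(stats::cor(t(rel[ok, , drop = FALSE]),
                                   t(seqs[nonflat, , drop = FALSE])))
  r <- matrix(r, nrow = length(ok))
  best <- apply(r, 1, which.max)   # which.max takes the first (lowest id) tie
  assignment <- data.frame(
    gene_id = rownames(series)[ok],
    profile_id = profiles$profile_id[nonflat][best],
    correlation = r[cbind(seq_along(best), best)],
    stringsAsFactors = FALSE)
  counts <- table(factor(assignment$profile_id,
                         levels = profiles$profile_id))
  list(assignment = assignment,
       counts = stats::setNames(as.integer(counts), names(counts)),
       excluded = excluded)
}

#' Profile significance by time-point permutation
#'
#' For every ordering of the T time points (all T! enumerated when
#' feasible, including the identity; otherwise \code{n_perm} sampled
#' orderings) all genes are re-assigned; the expected count E_p of each
#' profile is the mean over orderings, and the p-value is the
#' upper-tail binomial probability of observing at least the true count
#' among N assigned genes with success probability E_p / N.
#'
#' @param series,profiles as in \code{\link{assign_genes}}.
#' @param n_perm number of sampled orderings when T! exceeds
#'   \code{exhaustive_limit}.
#' @param exhaustive_limit largest T! enumerated exactly (default 720).
#' @param alpha significance cutoff (default 0.05).
#' @param seed seed for sampled orderings.
#' @return data.frame per profile: profile_id, observed, expected, p,
#'   significant.
#' @export
profile_significance <- function(series, profiles, n_perm = NULL,
                                 exhaustive_limit = 720, alpha = 0.05,
                                 seed = 1) {
  T <- ncol(profile_sequences(profiles))
  obs <- assign_genes(series, profiles)
  N <- nrow(obs$assignment)
  n_fact <- factorial(T)
  if (n_fact <= exhaustive_limit) {
    perms <- permutations_of(T)
  } else {
    if (is.null(n_perm))
      stop("T! too large for exhaustive enumeration; set n_perm")
    set.seed(seed)
    perms <- t(replicate(n_perm, sample.int(T)))
  }
  count_mat <- matrix(0, nrow(perms), nrow(profiles))
  for (i in seq_len(nrow(perms))) {
    cnt <- assign_genes(series[, perms[i, ], drop = FALSE],
                        profiles)$counts
    count_mat[i, ] <- cnt
  }
  expected <- colMeans(count_mat)
  observed <- obs$counts
  p <- vapply(seq_along(observed), function(j) {
    if (N == 0) return(1)
    pr <- min(max(expected[j] / N, 0), 1)
    max(stats::pbinom(observed[j] - 1, N, pr, lower.tail = FALSE),
        1e-300)
  }, numeric(1))
  data.frame(profile_id = profiles$profile_id,
             observed = as.integer(observed), expected = expected,
             p = p, significant = p < alpha,
             stringsAsFactors = FALSE)
}

# All permutations of 1..n as rows (n small).
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Group significant profiles by sequence similarity
#'
#' Single-linkage grouping: significant profiles whose sequences have
#' Pearson correlation at or above the threshold are linked, and
#' connected components become groups. Constant-sequence profiles (no
#' defined correlation) each form their own group.
#'
#' @param significance result of \code{\link{profile_significance}}.
#' @param profiles the profile catalogue.
#' @param correlation_threshold linkage threshold (default 0.7).
#' @return the significance data.frame with a \code{group_id} column
#'   (NA for non-significant profiles); groups are numbered in order of
#'   their best p-value.
#' @export
group_profiles <- function(significance, profiles,
                           correlation_threshold = 0.7) {
  sig_idx <- which(significance$significant)
  significance$group_id <- NA_integer_
  if (!length(sig_idx)) return(significance)
  seqs <- profile_sequences(profiles)[
    match(significance$profile_id[sig_idx], profiles$profile_id), ,
    drop = FALSE]
  n <- length(sig_idx)
  v <- apply(seqs, 1, stats::sd)
  adj <- diag(TRUE, n)
  if (sum(v > 0) >= 2) {
    r <- suppressWarnings(stats::cor(t(seqs[v > 0, , drop = FALSE])))
    link <- r >= correlation_threshold
    adj[v > 0, v > 0] <- link
  }
  # connected components by label propagation
  comp <- seq_len(n)
  repeat {
    new <- comp
    for (i in seq_len(n)) new[i] <- min(comp[adj[i, ]])
    if (identical(new, comp)) break
    comp <- new
  }
  # order groups by their most significant member
  best_p <- tapply(significance$p[sig_idx], comp, min)
  lab <- rank(best_p, ties.method = "first")
  significance$group_id[sig_idx] <- as.integer(
    lab[match(comp, as.integer(names(best_p)))])
  significance
}

#' Fold change between two time points
#'
#' Ratio of the per-time geometric-mean signals, reported with its
#' nearest-integer fold.
#'
#' @param gm genes x time-points matrix of positive geometric-mean
#'   signals (see \code{\link{timepoint_means}}).
#' @param t_from,t_to column names or indices.
#' @return data.frame gene_id, ratio, fold (rounded integer).
#' @examples
#' gm <- matrix(c(2402.5, 16708), 1, dimnames = list("CD866884",
#'                                                   c("0", "12")))
#' fold_change(gm, "0", "12")  # ratio 6.95, fold 7
#' @export
fold_change <- function(gm, t_from, t_to) {
  a <- gm[, t_from]
  b <- gm[, t_to]
  if (any(a <= 0 | b <= 0)) stop("signals must be positive")
  data.frame(gene_id = rownames(gm), ratio = b / a,
             fold = as.integer(round(b / a)),
             stringsAsFactors = FALSE)
}
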