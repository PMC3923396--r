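# Synthetic time-course microarray data with planted structure.
#
# The generator emulates a 5-time-point x 3-replicate germination design
# (0/12/24/36/48 HAI) at probe-set and probe-pair level, planting flat
# genes, temporal-profile genes, co-expression modules and enriched
# pathways so that every downstream stage of the pipeline can be scored
# against known truth.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator into a validated
#' list. Defaults emulate a five-stage germination time course
#' (0/12/24/36/48 hours after imbibition) with three biological
#' replicates per stage.
#'
#' @param n_genes total number of probe sets / genes.
#' @param n_timepoints number of time points (default 5).
#' @param n_replicates biological replicates per time point (default 3).
#' @param timepoints numeric labels for the time points, in hours after
#'   imbibition; length must equal \code{n_timepoints}.
#' @param frac_flat fraction of genes with no planted structure.
#' @param planted_profiles list of profile plants; each element is a
#'   list with \code{transitions} (integer vector of per-interval steps,
#'   length \code{n_timepoints - 1}), \code{n_genes}, and
#'   \code{amplitude} (log2 units per unit profile step).
#' @param noise_sd replicate noise standard deviation on the log2 scale.
#' @param baseline_log2_mean,baseline_log2_sd log-normal baseline
#'   expression parameters on the log2 scale (defaults 8 and 2, a
#'   plausible microarray signal scale).
#' @param n_probe_pairs PM/MM probe pairs per probe set (default 11).
#' @param n_pathways,n_enriched_pathways number of annotation terms and
#'   how many of them preferentially sample planted differential genes.
#' @param pathway_size genes per annotation term.
#' @param enrichment_odds odds ratio with which enriched terms favour
#'   planted-profile genes during sampling.
#' @param n_coexp_modules,module_size number and size of planted
#'   co-expression modules.
#' @param module_amplitude log2 amplitude of the shared module latent
#'   factor.
#' @param seed integer seed; identical configurations give identical
#'   outputs.
#' @return an object of class \code{"sim_config"} (a named list).
#' @examples
#' cfg <- sim_config(n_genes = 100, frac_flat = 1, seed = 1)
#' @export
sim_config <- function(n_genes,
                       n_timepoints = 5L,
                       n_replicates = 3L,
                       timepoints = c(0, 12, 24, 36, 48),
                       frac_flat = 1,
                       planted_profiles = list(),
                       noise_sd = 0.2,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 2,
                       n_probe_pairs = 11L,
                       n_pathways = 0L,
                       n_enriched_pathways = 0L,
                       pathway_size = 30L,
                       enrichment_odds = 8,
                       n_coexp_modules = 0L,
                       module_size = 0L,
                       module_amplitude = 1.5,
                       seed = 1L) {
  stopifnot(n_genes >= 1, n_timepoints >= 2, n_replicates >= 1,
            n_probe_pairs >= 3, noise_sd >= 0,
            frac_flat >= 0, frac_flat <= 1,
            n_pathways >= 0, n_enriched_pathways >= 0,
            n_coexp_modules >= 0, module_size >= 0)
  if (length(timepoints) != n_timepoints)
    stop("'timepoints' must have length n_timepoints")
  if (n_enriched_pathways > n_pathways)
    stop("more enriched pathways requested than pathways")
  n_profile <- sum(vapply(planted_profiles, function(p) p$n_genes, numeric(1)))
  n_module <- n_coexp_modules * module_size
  if (frac_flat * n_genes + n_profile + n_module > n_genes + 1e-9)
    stop("planted fractions exceed the total number of genes")
  for (p in planted_profiles) {
    if (length(p$transitions) != n_timepoints - 1L)
      stop("each planted profile needs n_timepoints - 1 transitions")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_timepoints = as.integer(n_timepoints),
    n_replicates = as.integer(n_replicates), timepoints = timepoints,
    frac_flat = frac_flat, planted_profiles = planted_profiles,
    noise_sd = noise_sd, baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    n_probe_pairs = as.integer(n_probe_pairs),
    n_pathways = as.integer(n_pathways),
    n_enriched_pathways = as.integer(n_enriched_pathways),
    pathway_size = as.integer(pathway_size),
    enrichment_odds = enrichment_odds,
    n_coexp_modules = as.integer(n_coexp_modules),
    module_size = as.integer(module_size),
    module_amplitude = module_amplitude,
    seed = as.integer(seed)), class = "sim_config")
}

#' Design table for a simulated experiment
#'
#' @param config a \code{sim_config}.
#' @return data.frame with columns \code{sample_id}, \code{time_hai},
#'   \code{replicate}; one row per array.
#' @export
sim_design <- function(config) {
  t_idx <- rep(seq_len(config$n_timepoints), each = config$n_replicates)
  rep_idx <- rep(seq_len(config$n_replicates), config$n_timepoints)
  data.frame(
    sample_id = sprintf("T%02d_r%d", config$timepoints[t_idx], rep_idx),
    time_hai = config$timepoints[t_idx],
    replicate = rep_idx,
    stringsAsFactors = FALSE)
}

#' Generate a gene-level expression matrix with planted truth
#'
#' Baseline log2 expression is drawn once per gene from a normal
#' distribution; planted-profile genes add \code{amplitude} times the
#' cumulative profile sequence; module genes share a per-sample latent
#' factor; independent Gaussian noise on the log2 scale is added per
#' sample. Signals are returned on the raw (positive) scale.
#'
#' @param config a \code{sim_config}.
#' @return list with \code{signal} (genes x samples positive matrix),
#'   \code{design} (see \code{\link{sim_design}}), and \code{truth}
#'   (data.frame: gene_id, class, profile_id, module_id).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  design <- sim_design(config)
  ns <- nrow(design)
  gene_id <- sprintf("G%05d", seq_len(n))

  n_profile <- vapply(config$planted_profiles, function(p) p$n_genes,
                      numeric(1))
  n_module <- config$n_coexp_modules * config$module_size
  n_planted <- sum(n_profile) + n_module
  if (n_planted > n) stop("planted genes exceed n_genes")

  class <- rep("flat", n)
  profile_id <- rep(NA_integer_, n)
  module_id <- rep(NA_integer_, n)
  idx <- 1L
  for (j in seq_along(config$planted_profiles)) {
    p <- config$planted_profiles[[j]]
    if (p$n_genes == 0) next
    rng <- idx:(idx + p$n_genes - 1L)
    class[rng] <- "profile"
    profile_id[rng] <- profile_id_from_transitions(p$transitions)
    idx <- idx + p$n_genes
  }
  for (m in seq_len(config$n_coexp_modules)) {
    if (config$module_size == 0) next
    rng <- idx:(idx + config$module_size - 1L)
    class[rng] <- "module"
    module_id[rng] <- m
    idx <- idx + config$module_size
  }

  baseline <- stats::rnorm(n, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  log2x <- matrix(baseline, n, ns)
  t_of_sample <- match(design$time_hai, config$timepoints)

  for (j in seq_along(config$planted_profiles)) {
    p <- config$planted_profiles[[j]]
    if (p$n_genes == 0) next
    pid <- profile_id_from_transitions(p$transitions)
    rows <- which(class == "profile" & profile_id == pid)
    seq_t <- c(0, cumsum(p$transitions))
    log2x[rows, ] <- log2x[rows, , drop = FALSE] +
      p$amplitude * matrix(seq_t[t_of_sample], length(rows), ns, byrow = TRUE)
  }
  for (m in seq_len(config$n_coexp_modules)) {
    rows <- which(module_id == m)
    if (!length(rows)) next
    latent <- stats::rnorm(ns)           # shared per-sample factor
    loading <- sample(c(-1, 1), length(rows), replace = TRUE)
    log2x[rows, ] <- log2x[rows, , drop = FALSE] +
      config$module_amplitude * outer(loading, latent)
  }
  if (config$noise_sd > 0)
    log2x <- log2x + matrix(stats::rnorm(n * ns, 0, config$noise_sd), n, ns)

  signal <- 2^log2x
  dimnames(signal) <- list(gene_id, design$sample_id)
  truth <- data.frame(gene_id = gene_id, class = class,
                      profile_id = profile_id, module_id = module_id,
                      stringsAsFactors = FALSE)
  list(signal = signal, design = design, truth = truth)
}

#' Generate probe-level PM/MM intensities from a gene-level matrix
#'
#' Each probe set receives \code{n_probe_pairs} probe pairs. Per-probe
#' affinities are drawn once from a log-normal and reused across arrays,
#' mimicking the probe-specific affinity confounding that summarization
#' must absorb. PM = background + affinity x signal + noise; MM =
#' background + crosshyb x affinity x signal + noise, floored at a small
#' positive value.
#'
#' @param config a \code{sim_config}.
#' @param expr result of \code{\link{generate_expression}}.
#' @param background additive optical background intensity.
#' @param crosshyb cross-hybridization fraction carried by MM probes.
#' @param probe_noise_sd additive intensity noise standard deviation.
#' @param affinity_log2_sd spread of per-probe log2 affinities.
#' @return data.frame with columns probe_set_id, probe_index, array_id,
#'   pm, mm.
#' @export
generate_probe_level <- function(config, expr, background = 100,
                                 crosshyb = 0.05, probe_noise_sd = 20,
                                 affinity_log2_sd = 0.5) {
  stopifnot(inherits(config, "sim_config"), probe_noise_sd >= 0,
            background >= 0, crosshyb >= 0)
  set.seed(config$seed + 1L)
  sig <- expr$signal
  n <- nrow(sig); ns <- ncol(sig); np <- config$n_probe_pairs
  affinity <- matrix(2^stats::rnorm(n * np, 0, affinity_log2_sd), n, np)
  out <- vector("list", ns)
  for (s in seq_len(ns)) {
    base_pm <- affinity * sig[, s]           # recycles signal down columns
    pm <- background + base_pm +
      matrix(stats::rnorm(n * np, 0, probe_noise_sd), n, np)
    mm <- background + crosshyb * base_pm +
      matrix(stats::rnorm(n * np, 0, probe_noise_sd), n, np)
    out[[s]] <- data.frame(
      probe_set_id = rep(rownames(sig), np),
      probe_index = rep(seq_len(np), each = n),
      array_id = colnames(sig)[s],
      pm = pmax(as.vector(pm), 0.5),
      mm = pmax(as.vector(mm), 0.5),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$array_id, res$probe_set_id, res$probe_index), ]
  rownames(res) <- NULL
  res
}

#' Generate annotations, interaction tables and an ortholog map
#'
#' Terms are sampled from the gene universe; the first
#' \code{n_enriched_pathways} terms favour planted-profile genes at the
#' configured odds ratio, so the enrichment stage has true positives to
#' find. Planted co-expression modules are emitted as fully connected
#' interaction edges plus random background edges, and a one-to-one
#' ortholog map translates gene ids into the interaction namespace.
#'
#' @param config a \code{sim_config}.
#' @param truth truth table from \code{\link{generate_expression}}.
#' @param n_background_edges random typed edges added beyond module
#'   cliques.
#' @param n_pathway_relations directed term-to-term relation edges.
#' @return list with \code{gene_sets} (named list of gene-id vectors),
#'   \code{interactions} (data.frame source, relation, target),
#'   \code{pathway_relations} (data.frame source, relation, target),
#'   \code{ortholog_map} (data.frame gene_id, ortholog_id).
#' @export
generate_annotations <- function(config, truth, n_background_edges = 200L,
                                 n_pathway_relations = 60L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  genes <- truth$gene_id
  de_like <- truth$class == "profile"
  ortholog_map <- data.frame(
    gene_id = genes,
    ortholog_id = sprintf("K%05d", seq_along(genes)),
    stringsAsFactors = FALSE)
  to_k <- stats::setNames(ortholog_map$ortholog_id, genes)

  gene_sets <- list()
  if (config$n_pathways > 0) {
    size <- min(config$pathway_size, length(genes))
    for (i in seq_len(config$n_pathways)) {
      w <- rep(1, length(genes))
      if (i <= config$n_enriched_pathways)
        w[de_like] <- config$enrichment_odds
      members <- sample(genes, size, prob = w)
      gene_sets[[sprintf("PW%03d", i)]] <- sort(members)
    }
  }

  # interaction edges are emitted in the ortholog namespace, the one
  # the signal-net stage works in after mapping DE genes
  edges <- list()
  mods <- unique(stats::na.omit(truth$module_id))
  for (m in mods) {
    members <- to_k[genes[which(truth$module_id == m)]]
    if (length(members) >= 2) {
      pairs <- utils::combn(unname(members), 2)
      edges[[length(edges) + 1L]] <- data.frame(
        source = pairs[1, ], relation = "b", target = pairs[2, ],
        stringsAsFactors = FALSE)
    }
  }
  if (n_background_edges > 0) {
    src <- unname(to_k[sample(genes, n_background_edges, replace = TRUE)])
    tgt <- unname(to_k[sample(genes, n_background_edges, replace = TRUE)])
    keep <- src != tgt
    edges[[length(edges) + 1L]] <- data.frame(
      source = src[keep],
      relation = sample(c("a", "p", "b", "c"), sum(keep), replace = TRUE),
      target = tgt[keep], stringsAsFactors = FALSE)
  }
  interactions <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), relation = character(),
               target = character(), stringsAsFactors = FALSE)

  pathway_relations <- data.frame(source = character(),
                                  relation = character(),
                                  target = character(),
                                  stringsAsFactors = FALSE)
  if (config$n_pathways >= 2 && n_pathway_relations > 0) {
    terms <- names(gene_sets)
    src <- sample(terms, n_pathway_relations, replace = TRUE)
    tgt <- sample(terms, n_pathway_relations, replace = TRUE)
    keep <- src != tgt
    pathway_relations <- unique(data.frame(
      source = src[keep], relation = "maplink", target = tgt[keep],
      stringsAsFactors = FALSE))
  }

  list(gene_sets = gene_sets, interactions = interactions,
       pathway_relations = pathway_relations, ortholog_map = ortholog_map)
}
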