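# Staged end-to-end pipeline: (simulate ->) summarize -> differential
# expression -> temporal profiles -> enrichment/path-net -> signal-net
# -> co-expression/k-core, with tab-delimited outputs and a run log.

#' Default run configuration
#'
#' Every stage parameter of the pipeline with its documented default.
#' The configuration round-trips losslessly through YAML.
#'
#' @param seed master seed for simulation and permutation draws.
#' @param out_dir output directory, or NULL to skip writing.
#' @param ... overrides for any default field.
#' @return a named list of class \code{"run_config"}.
#' @export
default_run_config <- function(seed = 1, out_dir = NULL, ...) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    # simulation (used when no input paths are given)
    sim = list(n_genes = 2000, frac_flat = 0.7, noise_sd = 0.2,
               amplitude = 1, n_pathways = 25, n_enriched_pathways = 3,
               n_coexp_modules = 2, module_size = 15),
    # input paths (all NULL -> simulate)
    paths = list(expression = NULL, design = NULL, gmt = NULL,
                 interactions = NULL, pathway_relations = NULL,
                 ortholog_map = NULL),
    # differential expression
    de = list(n_perm = 1000, p_threshold = 0.05, fdr_threshold = 0.05),
    # temporal profiles
    stc = list(c = 1, alpha = 0.05, group_r = 0.7),
    # enrichment
    enrich = list(p_threshold = 0.05, fdr_threshold = 0.05),
    # co-expression
    coexp = list(r_threshold = 0.8, significance_threshold = 0.05,
                 multiple_testing = "BH"))
  user <- list(...)
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    else cfg[[nm]] <- user[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return \code{read_run_config}: a \code{run_config};
#'   \code{write_run_config}: invisibly, the path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(default_run_config, c(cfg[setdiff(names(cfg),
                                            c("sim", "paths", "de", "stc",
                                              "enrich", "coexp"))],
                                cfg[intersect(names(cfg),
                                              c("sim", "paths", "de", "stc",
                                                "enrich", "coexp"))]))
}

#' @rdname read_run_config
#' @param config a \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in the order normalize/simulate, differential
#' expression, temporal profiles, enrichment and path-net, signal-net,
#' co-expression with k-core ranking. With no input paths configured a
#' synthetic dataset with planted structure is generated from the
#' configured seed, which makes \code{run_pipeline(default_run_config())}
#' a self-contained smoke test. Any stage failure aborts with the stage
#' name.
#'
#' @param config a \code{run_config}.
#' @return list with per-stage results and a \code{summary} list of
#'   headline counts; written to \code{config$out_dir} when set.
#' @export
run_pipeline <- function(config = default_run_config()) {
  inputs <- stage("input", pipeline_inputs(config))
  expr <- inputs$expr; design <- inputs$design

  de_res <- stage("differential_expression", {
    r <- rvm_f_test(expr, design)
    r <- permutation_fdr(r, expr, design, n_perm = config$de$n_perm,
                         seed = config$seed)
    select_de(r, expr, design, p_threshold = config$de$p_threshold,
              fdr_threshold = config$de$fdr_threshold)
  })

  gm <- timepoint_means(expr, design)
  stc_res <- stage("temporal_profiles", {
    profiles <- enumerate_profiles(ncol(gm), c = config$stc$c)
    series <- log2(gm[de_res$de_genes, , drop = FALSE])
    if (nrow(series) < 2) {
      NULL
    } else {
      asg <- assign_genes(series, profiles)
      sig <- profile_significance(series, profiles,
                                  alpha = config$stc$alpha,
                                  seed = config$seed)
      sig <- group_profiles(sig, profiles,
                            correlation_threshold = config$stc$group_r)
      list(profiles = profiles, assignment = asg, significance = sig)
    }
  })

  enrich_res <- stage("enrichment", {
    if (is.null(inputs$gene_sets) || !length(de_res$de_genes)) NULL
    else {
      tab <- pathway_enrichment(de_res$de_genes, rownames(expr),
                                inputs$gene_sets,
                                p_threshold = config$enrich$p_threshold,
                                fdr_threshold = config$enrich$fdr_threshold)
      pn <- if (!is.null(inputs$pathway_relations) &&
                any(tab$significant))
        build_path_net(tab$term[tab$significant],
                       inputs$pathway_relations)
      else NULL
      list(table = tab, path_net = pn)
    }
  })

  signal_res <- stage("signal_net", {
    if (is.null(inputs$interactions) || !length(de_res$de_genes)) NULL
    else build_signal_net(de_res$de_genes, inputs$ortholog_map,
                          inputs$interactions)
  })

  coexp_res <- stage("coexpression", {
    if (length(de_res$de_genes) < 2) NULL
    else {
      x <- log2(expr[de_res$de_genes, design$sample_id, drop = FALSE])
      edges <- coexpression_edges(
        x, r_threshold = config$coexp$r_threshold,
        significance_threshold = config$coexp$significance_threshold,
        multiple_testing = config$coexp$multiple_testing)
      ranks <- rank_core_genes(de_res$de_genes, edges)
      list(edges = edges, ranks = ranks)
    }
  })

  summary <- list(
    n_genes = nrow(expr),
    n_samples = ncol(expr),
    n_de = length(de_res$de_genes),
    updown = de_res$updown,
    n_significant_profiles = if (!is.null(stc_res))
      sum(stc_res$significance$significant) else 0L,
    n_profile_groups = if (!is.null(stc_res))
      length(unique(stats::na.omit(stc_res$significance$group_id)))
    else 0L,
    n_significant_pathways = if (!is.null(enrich_res))
      sum(enrich_res$table$significant) else 0L,
    n_coexp_edges = if (!is.null(coexp_res))
      nrow(coexp_res$edges) else 0L,
    main_core = if (!is.null(coexp_res))
      max(c(coexp_res$ranks$core, 0L)) else 0L,
    seed = config$seed)

  result <- list(config = config, inputs = inputs, de = de_res,
                 stc = stc_res, enrichment = enrich_res,
                 signal_net = signal_res, coexpression = coexp_res,
                 summary = summary)
  if (!is.null(config$out_dir))
    stage("write_output", write_pipeline_output(result, config$out_dir))
  result
}

# Resolve inputs: read the configured paths, or simulate a dataset
# with planted structure when none are given.
pipeline_inputs <- function(config) {
  p <- config$paths
  if (!is.null(p$expression)) {
    expr <- read_expression_matrix(p$expression)
    design <- read_design(p$design)
    gene_sets <- if (!is.null(p$gmt)) read_gmt(p$gmt) else NULL
    interactions <- if (!is.null(p$interactions))
      read_sif(p$interactions) else NULL
    relations <- if (!is.null(p$pathway_relations))
      read_sif(p$pathway_relations) else NULL
    omap <- if (!is.null(p$ortholog_map))
      utils::read.delim(p$ortholog_map, stringsAsFactors = FALSE)
    else NULL
    return(list(expr = expr, design = design, gene_sets = gene_sets,
                interactions = interactions, pathway_relations = relations,
                ortholog_map = omap, truth = NULL))
  }
  s <- config$sim
  n_prof <- max(0, floor((1 - s$frac_flat) * s$n_genes) -
                  s$n_coexp_modules * s$module_size)
  quarter <- n_prof %/% 4
  planted <- list(
    list(transitions = c(1, 1, 1, 1), n_genes = quarter,
         amplitude = s$amplitude),
    list(transitions = c(-1, -1, -1, -1), n_genes = quarter,
         amplitude = s$amplitude),
    list(transitions = c(1, 1, -1, -1), n_genes = quarter,
         amplitude = s$amplitude),
    list(transitions = c(-1, -1, 1, 1),
         n_genes = n_prof - 3 * quarter, amplitude = s$amplitude))
  cfg <- sim_config(
    n_genes = s$n_genes, frac_flat = 0,
    planted_profiles = planted, noise_sd = s$noise_sd,
    n_pathways = s$n_pathways,
    n_enriched_pathways = s$n_enriched_pathways,
    n_coexp_modules = s$n_coexp_modules, module_size = s$module_size,
    seed = config$seed)
  expr <- generate_expression(cfg)
  ann <- generate_annotations(cfg, expr$truth)
  list(expr = expr$signal, design = expr$design,
       gene_sets = ann$gene_sets, interactions = ann$interactions,
       pathway_relations = ann$pathway_relations,
       ortholog_map = ann$ortholog_map, truth = expr$truth)
}

# Write per-stage tables plus a machine-readable summary and a log.
write_pipeline_output <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- sprintf("# wheatgerm run: seed=%s", result$config$seed)
  wt <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(prov, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  wt(result$de$table, "differential_expression.tsv")
  wt(result$de$updown, "updown_counts.tsv")
  if (!is.null(result$stc)) {
    wt(result$stc$assignment$assignment, "profile_assignment.tsv")
    wt(result$stc$significance, "profile_significance.tsv")
  }
  if (!is.null(result$enrichment))
    wt(result$enrichment$table, "pathway_enrichment.tsv")
  if (!is.null(result$enrichment$path_net))
    wt(result$enrichment$path_net$nodes, "path_net_nodes.tsv")
  if (!is.null(result$signal_net))
    wt(result$signal_net$nodes, "signal_net_nodes.tsv")
  if (!is.null(result$coexpression)) {
    wt(result$coexpression$edges, "coexpression_edges.tsv")
    wt(result$coexpression$ranks, "core_ranks.tsv")
  }
  s <- result$summary
  flat <- list(n_genes = s$n_genes, n_samples = s$n_samples,
               n_de = s$n_de,
               n_significant_profiles = s$n_significant_profiles,
               n_profile_groups = s$n_profile_groups,
               n_significant_pathways = s$n_significant_pathways,
               n_coexp_edges = s$n_coexp_edges,
               main_core = s$main_core, seed = s$seed)
  yaml::write_yaml(flat, file.path(out_dir, "summary.yaml"))
  invisible(out_dir)
}
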