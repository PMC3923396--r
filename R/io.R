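# Readers and writers for the pipeline's interchange formats:
# tab-delimited expression matrices with a design table, GMT gene-set
# files, and SIF-like typed edge tables.

#' Read a tab-delimited expression matrix
#'
#' First column holds probe-set/gene ids, header holds sample ids.
#' Duplicate ids (a known quirk of some chip annotations) are retained
#' and disambiguated with ".dupN" suffixes, with a warning. Non-numeric
#' cells raise an error naming the offending row and column.
#'
#' @param path file path.
#' @return numeric matrix with unique row names.
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character",
                           comment.char = "#")
  ids <- raw[[1]]
  dat <- raw[-1]
  for (j in seq_along(dat)) {
    x <- suppressWarnings(as.numeric(dat[[j]]))
    bad <- which(is.na(x) & !is.na(dat[[j]]) & dat[[j]] != "NA")
    if (length(bad))
      stop("non-numeric cell at row '", ids[bad[1]], "', column '",
           names(dat)[j], "': ", dat[[j]][bad[1]])
    dat[[j]] <- x
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sum(dup), " duplicated probe-set ids; ",
            "suffix-disambiguated with .dupN")
    ids <- make.unique(ids, sep = ".dup")
  }
  m <- as.matrix(dat)
  rownames(m) <- ids
  m
}

#' Write an expression matrix as tab-delimited text
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @param id_column header for the id column (default "probe_set_id").
#' @export
write_expression_matrix <- function(mat, path,
                                    id_column = "probe_set_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a design table (sample, time, replicate)
#'
#' @param path tab-delimited file with columns sample_id, time_hai,
#'   replicate.
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_hai", "replicate")
  if (!all(need %in% names(d)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  d
}

#' Read a GMT gene-set file
#'
#' Each line: term id, description, then member gene ids, all
#' tab-separated. Empty terms raise an error.
#'
#' @param path file path.
#' @return named list of character vectors; attribute
#'   \code{descriptions}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  desc <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "",
                 character(1))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  if (any(!lengths(sets)))
    stop("empty gene set: ", ids[which(!lengths(sets))[1]])
  names(sets) <- ids
  attr(sets, "descriptions") <- stats::setNames(desc, ids)
  sets
}

#' Write a GMT gene-set file
#'
#' @param gene_sets named list of member-id vectors.
#' @param path output path.
#' @param descriptions optional named descriptions.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  lines <- vapply(names(gene_sets), function(term) {
    d <- if (!is.null(descriptions)) descriptions[[term]] else term
    paste(c(term, d, gene_sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read a SIF-like typed edge table
#'
#' Whitespace-delimited: source, relation code, target, optional
#' weight. Self-loops are dropped (counted in the \code{n_self_loops}
#' attribute); duplicate edges are collapsed with weight summation;
#' unknown relation codes are kept with a warning.
#'
#' @param path file path.
#' @param known_relations codes not warned about.
#' @return data.frame source, target, relation, directed, weight.
#' @export
read_sif <- function(path, known_relations = c("a", "p", "b", "c",
                                               "e", "i", "maplink")) {
  raw <- utils::read.table(path, stringsAsFactors = FALSE,
                           col.names = c("source", "relation", "target",
                                         "weight")[1:count_sif_cols(path)],
                           fill = TRUE)
  if (is.null(raw$weight)) raw$weight <- 1
  unknown <- setdiff(unique(raw$relation), known_relations)
  if (length(unknown))
    warning("unknown relation codes kept: ",
            paste(unknown, collapse = ", "))
  cl <- clean_edges(data.frame(source = raw$source, target = raw$target,
                               relation = raw$relation,
                               weight = raw$weight,
                               stringsAsFactors = FALSE))
  out <- cl$edges
  attr(out, "n_self_loops") <- cl$n_self_loops
  attr(out, "n_collapsed") <- cl$n_collapsed
  out
}

count_sif_cols <- function(path) {
  first <- readLines(path, n = 1)
  min(length(strsplit(trimws(first), "[ \t]+")[[1]]), 4L)
}

#' Write a SIF-like edge table
#'
#' @param edges data.frame with source, relation, target (and optional
#'   weight).
#' @param path output path.
#' @export
write_sif <- function(edges, path) {
  cols <- c("source", "relation", "target")
  if (!is.null(edges$weight) && !all(edges$weight == 1))
    utils::write.table(edges[c(cols, "weight")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  else
    utils::write.table(edges[cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
}

#' Expression values of germination marker genes
#'
#' Per-stage geometric-mean signal values of 21 wheat ESTs spanning
#' signaling, development, glycolysis/fermentation, starch mobilization,
#' transport and protein turnover, sampled at 0/12/24/36/48 hours after
#' imbibition. Shipped as a worked example for fold-change and
#' category-aggregation calculations.
#'
#' @return list with \code{signal} (genes x 5 stages matrix) and
#'   \code{annotation} (named character vector).
#' @examples
#' gm <- germination_markers()$signal
#' fold_change(gm, "0", "12")["CD866884", ]
#' @export
germination_markers <- function() {
  path <- system.file("extdata", "germination_marker_signals.tsv",
                      package = "wheatgerm", mustWork = TRUE)
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -(1:2)])
  rownames(m) <- d$gene_id
  list(signal = m,
       annotation = stats::setNames(d$annotation, d$gene_id))
}
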