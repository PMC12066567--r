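# TSV / GMT readers and writers shared across the pipeline.
# Numeric matrices are written with %.17g so a write/read cycle is
# bit-exact for doubles.

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a gene x sample expression matrix as TSV
#'
#' First column is `gene`, remaining columns are samples. Doubles are written
#' with enough digits to round-trip exactly.
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m),
                   matrix(.fmt_num(m), nrow(m), ncol(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1L] <- colnames(m)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample expression matrix from TSV
#'
#' @param path TSV with a header row and a leading `gene` column.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- toupper(df[[1L]])
  m
}

#' Write sample labels as TSV
#' @param labels Named character vector (`"case"`/`"control"` per sample id).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(
    data.frame(sample = names(labels), group = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample labels from TSV
#' @param path TSV with columns `sample` and `group`.
#' @return Named character vector.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$group, df$sample)
}

#' Read a two-column annotation TSV (gene, value)
#' @param path TSV with a header; first column gene symbols, second numeric.
#' @return Named numeric vector keyed by uppercased gene symbol.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2L]]), toupper(df[[1L]]))
}

#' Write a two-column annotation TSV
#' @param x Named numeric vector.
#' @param path Output path.
#' @param value_name Header for the value column.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(x, path, value_name = "value") {
  df <- data.frame(gene = names(x), value = .fmt_num(unname(x)))
  names(df)[2L] <- value_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `set_id<TAB>description<TAB>gene...`.
#'
#' @param path GMT file path.
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    toupper(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L), USE.NAMES = FALSE)
  sets
}

#' Write gene sets as GMT
#' @param sets Named list of character gene vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(id, desc, genes)
    paste(c(id, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

# gene -> set-membership list from a GMT-style list of sets
.invert_gmt <- function(sets, genes) {
  out <- stats::setNames(vector("list", length(genes)), genes)
  for (i in seq_along(genes)) out[[i]] <- character(0)
  for (s in names(sets)) {
    hit <- intersect(sets[[s]], genes)
    for (g in hit) out[[g]] <- c(out[[g]], s)
  }
  lapply(out, sort)
}

#' Read a gene x tissue specificity-score matrix from TSV
#' @param path TSV with a `gene` column followed by one column per tissue.
#' @return Numeric matrix.
#' @export
read_ts_matrix <- function(path) read_expression_tsv(path)

#' Read a dataset manifest TSV
#'
#' Columns: `disease`, `dataset_id`, `expr_path`, `labels_path`, `n_cases`,
#' `n_controls`. Paths may be relative to the manifest location.
#'
#' @param path Manifest TSV path.
#' @return A data.frame; attribute `"dir"` holds the manifest directory.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("disease", "dataset_id", "n_cases", "n_controls")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  for (col in c("n_cases", "n_controls")) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop(sprintf("manifest line %d: non-numeric %s", bad[1L] + 1L, col))
    df[[col]] <- as.integer(df[[col]])
  }
  attr(df, "dir") <- dirname(path)
  df
}

#' Read PPI degrees from a degree TSV or an edge-list TSV
#'
#' A two-column file is treated as precomputed `gene<TAB>degree` when the
#' second column is numeric, otherwise as an edge list (`node_a`, `node_b`,
#' optional weight) whose node degrees are computed with igraph.
#'
#' @param path Input TSV.
#' @return Named numeric degree vector.
#' @export
read_ppi_degrees <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) == 2L && is.numeric(df[[2L]])) {
    return(stats::setNames(as.numeric(df[[2L]]), toupper(df[[1L]])))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = toupper(df[[1L]]), to = toupper(df[[2L]])),
    directed = FALSE)
  deg <- igraph::degree(g)
  stats::setNames(as.numeric(deg), names(deg))
}

#' Write a simulated study to disk as plain-text fixtures
#'
#' Writes one expression TSV and one labels TSV per dataset, the annotation
#' TSVs, the pathway GMT, the tissue-score matrix, and a manifest TSV
#' (disease, dataset_id, expr_path, labels_path, n_cases, n_controls).
#' Matrices round-trip bit-exactly through the package readers.
#'
#' @param datasets Named list of [expression_dataset()] objects.
#' @param bundle An [gen_annotation_bundle()] result.
#' @param out_dir Output directory (created if needed).
#' @return Path of the manifest TSV, invisibly.
#' @export
write_fixtures <- function(datasets, bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(datasets, function(ds) {
    expr <- sprintf("%s_expr.tsv", ds$dataset_id)
    lab <- sprintf("%s_labels.tsv", ds$dataset_id)
    write_expression_tsv(ds$matrix, file.path(out_dir, expr))
    write_labels_tsv(ds$labels, file.path(out_dir, lab))
    data.frame(disease = ds$disease, dataset_id = ds$dataset_id,
               expr_path = expr, labels_path = lab,
               n_cases = sum(ds$labels == "case"),
               n_controls = sum(ds$labels == "control"))
  })
  manifest <- do.call(rbind, rows)
  write_annotation_tsv(bundle$variant_count,
                       file.path(out_dir, "variant_counts.tsv"), "variant_count")
  write_annotation_tsv(bundle$pli, file.path(out_dir, "pli.tsv"), "pli")
  write_annotation_tsv(bundle$degree, file.path(out_dir, "ppi_degree.tsv"),
                       "degree")
  # GMT wants set -> genes; the bundle stores gene -> sets
  all_sets <- sort(unique(unlist(bundle$pathways, use.names = FALSE)))
  sets <- lapply(stats::setNames(all_sets, all_sets), function(s)
    names(bundle$pathways)[vapply(bundle$pathways, function(p) s %in% p,
                                  logical(1L))])
  write_gmt(sets, file.path(out_dir, "pathways.gmt"))
  write_expression_tsv(bundle$ts_matrix, file.path(out_dir, "ts_matrix.tsv"))
  manifest_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest_path)
}

#' Load the datasets referenced by a manifest
#' @param manifest A [read_manifest()] data.frame (or a path to one).
#' @return Named list of [expression_dataset()] objects.
#' @export
load_manifest_datasets <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir <- attr(manifest, "dir") %||% "."
  if (!all(c("expr_path", "labels_path") %in% names(manifest)))
    stop("manifest has no expression/label paths to load")
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    expr <- file.path(dir, manifest$expr_path[i])
    lab <- file.path(dir, manifest$labels_path[i])
    for (p in c(expr, lab)) if (!file.exists(p)) stop("missing input file: ", p)
    out[[manifest$dataset_id[i]]] <- expression_dataset(
      read_expression_tsv(expr), read_labels_tsv(lab),
      manifest$dataset_id[i], manifest$disease[i])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
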