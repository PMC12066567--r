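#' Construct an expression dataset
#'
#' Bundles one study's gene x sample expression matrix with its case/control
#' labels. Gene symbols are uppercased and must be unique within the dataset;
#' every sample must carry a label.
#'
#' @param matrix Numeric gene x sample matrix with row and column names.
#'   Values are non-negative intensities; `NA` marks missing measurements.
#' @param labels Named character vector mapping every sample id to
#'   `"case"` or `"control"`.
#' @param dataset_id Identifier of the study (e.g. a GEO accession).
#' @param disease Disease identifier the study belongs to.
#' @param missing_mask Optional logical matrix of the same shape recording
#'   which entries were truly missing before zero-encoding (used by the
#'   synthetic generator's bookkeeping; not consumed by the pipeline).
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(matrix, labels, dataset_id, disease,
                               missing_mask = NULL) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("expression matrix needs gene rownames and sample colnames")
  rownames(matrix) <- toupper(rownames(matrix))
  if (anyDuplicated(rownames(matrix)))
    stop("gene symbols must be unique within a dataset")
  if (!all(colnames(matrix) %in% names(labels)))
    stop("every sample needs a case/control label")
  labels <- labels[colnames(matrix)]
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  if (any(matrix < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  structure(
    list(matrix = matrix, labels = labels,
         dataset_id = as.character(dataset_id),
         disease = as.character(disease),
         missing_mask = missing_mask),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("<ExpressionDataset %s (%s): %d genes x %d samples (%d case / %d control)>\n",
              x$dataset_id, x$disease, nrow(x$matrix), ncol(x$matrix),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' Construct a disease profile
#'
#' A merged, row-normalized expression matrix for one disease. Columns from
#' different source datasets are tracked through `batch`; entries masked as
#' outliers are `NA` and excluded from all downstream statistics.
#'
#' @param matrix Numeric gene x sample matrix (post-normalization values lie
#'   in [0, 1] until batch correction, which may move them outside).
#' @param labels Named character vector, `"case"`/`"control"` per sample.
#' @param batch Named character vector mapping each sample to its source
#'   dataset id.
#' @param disease Disease identifier.
#' @param log Optional list of provenance entries (per-step feature counts,
#'   masking counts).
#' @return An object of class `DiseaseProfile`.
#' @export
disease_profile <- function(matrix, labels, batch, disease, log = list()) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (!all(colnames(matrix) %in% names(labels)))
    stop("every sample needs a label")
  if (!all(colnames(matrix) %in% names(batch)))
    stop("every sample needs a batch id")
  structure(
    list(matrix = matrix, labels = labels[colnames(matrix)],
         batch = batch[colnames(matrix)], disease = as.character(disease),
         log = log),
    class = "DiseaseProfile")
}

#' @export
print.DiseaseProfile <- function(x, ...) {
  cat(sprintf("<DiseaseProfile %s: %d genes x %d samples, %d batches, %d masked entries>\n",
              x$disease, nrow(x$matrix), ncol(x$matrix),
              length(unique(x$batch)), sum(is.na(x$matrix))))
  invisible(x)
}
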