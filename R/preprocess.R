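#' Filter lowly observed genes
#'
#' Removes genes whose zero-or-missing fraction strictly exceeds
#' `max_zero_frac` (zeros and missing values are one state at this stage).
#' Sample set and gene order are unchanged; the result may be empty.
#'
#' @param ds An [expression_dataset()].
#' @param max_zero_frac Maximum tolerated zero/missing fraction per gene
#'   (default 0.75; a gene at exactly the threshold is retained).
#' @return Filtered `ExpressionDataset`.
#' @export
filter_features <- function(ds, max_zero_frac = 0.75) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  .assert_fraction(max_zero_frac, "max_zero_frac")
  frac <- rowMeans(ds$matrix == 0 | is.na(ds$matrix))
  keep <- frac <= max_zero_frac
  ds$matrix <- ds$matrix[keep, , drop = FALSE]
  if (!is.null(ds$missing_mask))
    ds$missing_mask <- ds$missing_mask[keep, , drop = FALSE]
  ds
}

#' Impute missing expression values with zeros
#'
#' @param ds An [expression_dataset()].
#' @return Dataset with every `NA` replaced by 0; observed entries untouched.
#' @export
impute_missing <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (anyNA(ds$matrix)) ds$matrix[is.na(ds$matrix)] <- 0
  ds
}

#' Row-wise min-max normalize a dataset
#'
#' Applies [minmax_normalize()] to every gene row, putting each gene on a
#' common [0, 1] scale within the dataset.
#'
#' @param ds An [expression_dataset()].
#' @return Normalized `ExpressionDataset`.
#' @export
normalize_dataset <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  ds$matrix <- .rowwise_minmax(ds$matrix)
  ds
}

#' Merge datasets into a disease profile
#'
#' Genes are intersected across datasets (merging "by gene names" without
#' imputing whole missing studies), columns concatenated with the source
#' dataset id as batch label, and each merged gene row min-max normalized
#' across all samples.
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param cross_disease Allow mixing diseases (used for the pan-disease
#'   profile); otherwise all datasets must share one disease.
#' @param cases_only Drop control columns before merging (the pan-disease
#'   profile merges case samples only).
#' @param disease Profile label; defaults to the common disease or
#'   `"pan"` for cross-disease merges.
#' @return A [disease_profile()].
#' @export
merge_by_gene <- function(datasets, cross_disease = FALSE, cases_only = FALSE,
                          disease = NULL) {
  stopifnot(length(datasets) >= 1L)
  dis <- unique(vapply(datasets, function(d) d$disease, character(1L)))
  if (length(dis) > 1L && !cross_disease)
    stop("datasets span multiple diseases; set cross_disease = TRUE to merge")
  if (is.null(disease)) disease <- if (length(dis) == 1L) dis else "pan"
  if (cases_only)
    datasets <- lapply(datasets, function(d) {
      keep <- names(d$labels)[d$labels == "case"]
      d$matrix <- d$matrix[, keep, drop = FALSE]
      d$labels <- d$labels[keep]
      d
    })
  genes <- Reduce(intersect, lapply(datasets, function(d) rownames(d$matrix)))
  if (length(genes) == 0L)
    stop("empty gene intersection across datasets: no profile can be built")
  m <- do.call(cbind, lapply(datasets, function(d)
    d$matrix[genes, , drop = FALSE]))
  labels <- do.call(c, unname(lapply(datasets, function(d) d$labels)))
  batch <- do.call(c, unname(lapply(datasets, function(d)
    stats::setNames(rep(d$dataset_id, length(d$labels)), names(d$labels)))))
  if (anyDuplicated(colnames(m)))
    stop("sample ids collide across datasets; make them unique first")
  disease_profile(.rowwise_minmax(m), labels, batch, disease,
                  log = list(n_genes_merged = length(genes),
                             n_datasets = length(datasets)))
}

#' Remove batch effects from a merged profile
#'
#' Parametric empirical-Bayes location/scale adjustment (the ComBat model,
#' via \code{sva::ComBat}): per-gene standardization, per-batch additive and
#' multiplicative effects estimated, shrunk toward common priors and
#' removed. Adjusted values may leave [0, 1]; they are deliberately not
#' re-normalized. A single-batch profile is returned unchanged; genes with
#' zero overall variance bypass adjustment. If any batch has fewer than two
#' samples, ComBat's location-only (mean-only) fit is used and a warning is
#' raised.
#'
#' @param profile A [disease_profile()] without masked entries.
#' @return Batch-corrected `DiseaseProfile`.
#' @export
batch_correct <- function(profile) {
  stopifnot(inherits(profile, "DiseaseProfile"))
  if (anyNA(profile$matrix))
    stop("batch_correct expects an unmasked profile (run it before mask_outliers)")
  batches <- profile$batch
  if (length(unique(batches)) < 2L) return(profile)
  sizes <- table(batches)
  mean_only <- any(sizes < 2L)
  if (mean_only)
    warning("batch with < 2 samples: falling back to location-only adjustment")
  m <- profile$matrix
  vr <- apply(m, 1L, stats::var)
  adj <- vr > 0
  if (sum(adj) >= 2L) {
    corrected <- suppressMessages(
      sva::ComBat(dat = m[adj, , drop = FALSE], batch = batches,
                  par.prior = TRUE, mean.only = mean_only))
    m[adj, ] <- corrected
  }
  profile$matrix <- m
  profile$log$batch_corrected <- TRUE
  profile
}

#' Mask per-gene outliers outside a percentile band
#'
#' For each gene, values strictly below the `lo` quantile or strictly above
#' the `hi` quantile (linear-interpolation quantiles, R type 7) are set to
#' `NA`. Masking, rather than sample deletion, keeps labels aligned across
#' genes; masked entries are excluded from all downstream statistics.
#'
#' @param profile A [disease_profile()].
#' @param lo,hi Percentile bounds (defaults 0.10 and 0.90).
#' @return Profile with outliers masked; masking counts appended to the log.
#' @export
mask_outliers <- function(profile, lo = 0.10, hi = 0.90) {
  stopifnot(inherits(profile, "DiseaseProfile"))
  .assert_fraction(lo, "lo"); .assert_fraction(hi, "hi")
  if (lo >= hi) stop("'lo' must be strictly below 'hi'")
  m <- profile$matrix
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    q <- stats::quantile(x, c(lo, hi), na.rm = TRUE, names = FALSE, type = 7)
    m[i, which(x < q[1L] | x > q[2L])] <- NA
  }
  profile$log$n_masked <- sum(is.na(m)) - sum(is.na(profile$matrix))
  profile$matrix <- m
  profile
}

#' Build a disease profile from raw datasets
#'
#' Runs the per-disease preprocessing chain: feature filter, zero
#' imputation, per-dataset row min-max, gene-intersection merge with a
#' second row min-max, ComBat batch correction (when more than one dataset
#' contributes), and percentile outlier masking. Per-step feature counts are
#' recorded in the profile log.
#'
#' @param datasets List of [expression_dataset()] objects for one disease.
#' @param max_zero_frac Feature-filter threshold, see [filter_features()].
#' @param lo,hi Outlier band, see [mask_outliers()].
#' @param correct_batch Apply [batch_correct()] when >1 batch (default TRUE).
#' @return A [disease_profile()].
#' @export
build_disease_profile <- function(datasets, max_zero_frac = 0.75,
                                  lo = 0.10, hi = 0.90, correct_batch = TRUE) {
  raw_counts <- vapply(datasets, function(d) nrow(d$matrix), integer(1L))
  pre <- lapply(datasets, function(d)
    normalize_dataset(impute_missing(filter_features(d, max_zero_frac))))
  filt_counts <- vapply(pre, function(d) nrow(d$matrix), integer(1L))
  profile <- merge_by_gene(pre)
  if (correct_batch && length(unique(profile$batch)) > 1L)
    profile <- batch_correct(profile)
  profile <- mask_outliers(profile, lo, hi)
  profile$log$n_features_raw <- raw_counts
  profile$log$n_features_filtered <- filt_counts
  profile
}

#' Case-only pan-disease profile
#'
#' Merges the case samples of every dataset across diseases (controls are
#' excluded at the label level), with the same normalization, batch
#' correction and outlier masking as a single-disease profile.
#'
#' @inheritParams build_disease_profile
#' @return A [disease_profile()] labelled `"pan"` (all samples are cases).
#' @export
build_pan_profile <- function(datasets, max_zero_frac = 0.75,
                              lo = 0.10, hi = 0.90, correct_batch = TRUE) {
  pre <- lapply(datasets, function(d)
    normalize_dataset(impute_missing(filter_features(d, max_zero_frac))))
  profile <- merge_by_gene(pre, cross_disease = TRUE, cases_only = TRUE,
                           disease = "pan")
  if (correct_batch && length(unique(profile$batch)) > 1L)
    profile <- batch_correct(profile)
  mask_outliers(profile, lo, hi)
}
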