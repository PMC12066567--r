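# Six per-gene evidence layers, each mapped into [0, 1] over the disease's
# retained gene universe. Genes missing from an annotation source score 0
# on that layer (absence of evidence contributes no risk).

.align_values <- function(x, genes, fill = 0) {
  out <- stats::setNames(rep(fill, length(genes)), genes)
  hit <- intersect(names(x), genes)
  out[hit] <- x[hit]
  out
}

#' ClinVar variant-load score (Gc)
#'
#' `Gc = minmax(log(count + 1))`. The log damps extreme variant counts; the
#' min-max over the gene universe brings the score into [0, 1]. The result
#' is invariant to the logarithm base (an affine factor absorbed by
#' min-max). All-equal counts degenerate to all zeros.
#'
#' @param variant_count Named non-negative counts (per gene).
#' @param genes Gene universe; genes without a count score 0.
#' @return Named numeric vector in [0, 1].
#' @export
clinvar_score <- function(variant_count, genes = names(variant_count)) {
  x <- .align_values(variant_count, genes)
  if (any(x < 0)) stop("variant counts must be non-negative")
  .log_minmax(x, 1)
}

#' pLI constraint score (Gp)
#'
#' `Gp = minmax(log(pLI + eps))` with a small `eps` preventing `log(0)`.
#'
#' @param pli Named pLI values in [0, 1].
#' @param genes Gene universe; genes without a value score as pLI 0.
#' @param eps Smoothing constant (default 1e-12).
#' @return Named numeric vector in [0, 1].
#' @export
pli_score <- function(pli, genes = names(pli), eps = 1e-12) {
  x <- .align_values(pli, genes)
  if (any(x < 0 | x > 1)) stop("pLI values must lie in [0, 1]")
  .log_minmax(x, eps)
}

#' Transcriptome significance score (GT)
#'
#' `GT = 1 - p_value` from the disease's differential expression test.
#' An undefined p-value (group empty after masking) carries no evidence and
#' scores 0.
#'
#' @param p_value Named p-values in [0, 1] (NA/NaN allowed).
#' @param genes Gene universe; genes without a p-value score 0.
#' @return Named numeric vector in [0, 1].
#' @export
transcriptome_score <- function(p_value, genes = names(p_value)) {
  x <- .align_values(p_value, genes, fill = 1)
  x[is.na(x)] <- 1
  if (any(x < 0 | x > 1)) stop("p-values must lie in [0, 1]")
  1 - x
}

#' Proteome connectivity score (GP)
#'
#' `GP = minmax(log(degree + 1))` where degree is the number of interaction
#' partners of the gene's protein in the PPI network. Genes absent from the
#' network have degree 0.
#'
#' @param degree Named non-negative degrees.
#' @param genes Gene universe.
#' @return Named numeric vector in [0, 1].
#' @export
proteome_score <- function(degree, genes = names(degree)) {
  x <- .align_values(degree, genes)
  if (any(x < 0)) stop("degrees must be non-negative")
  .log_minmax(x, 1)
}

#' Metabolome dominant-pathway score (GM)
#'
#' The dominant pathway is the single pathway with the highest membership
#' count over the gene universe (ties broken lexicographically by pathway
#' id). With `N_total` the number of genes annotated to at least one
#' pathway and `n_dominant` the dominant pathway's membership count,
#' `GM(g) = n_dominant / N_total` when the gene belongs to the dominant
#' pathway and 0 otherwise — structurally at most two distinct values.
#'
#' @param pathways Named list: gene -> character vector of pathway ids
#'   (possibly empty).
#' @param genes Gene universe; genes without annotation have no pathways.
#' @return Named numeric vector in [0, 1].
#' @export
metabolome_score <- function(pathways, genes = names(pathways)) {
  memb <- stats::setNames(vector("list", length(genes)), genes)
  hit <- intersect(names(pathways), genes)
  memb[hit] <- pathways[hit]
  memb <- lapply(memb, function(p) if (is.null(p)) character(0) else p)
  counts <- table(unlist(memb, use.names = FALSE))
  n_total <- sum(lengths(memb) > 0L)
  gm <- stats::setNames(numeric(length(genes)), genes)
  if (length(counts) == 0L || n_total == 0L) return(gm)
  top <- sort(names(counts)[counts == max(counts)])[1L]
  in_dom <- vapply(memb, function(p) top %in% p, logical(1L))
  gm[in_dom] <- as.numeric(counts[[top]]) / n_total
  gm
}

#' Tissue specificity score (GTS)
#'
#' With `TStotal(g)` the sum of the gene's per-tissue specificity scores and
#' `TScount(g)` the number of tissues where the score strictly exceeds
#' `threshold`, `GTS = (TScount / ts_norm) * minmax(TStotal)`. `ts_norm` is
#' the total number of tissues in the reference (32 types by default), so
#' GTS lies in [0, TScount_max / ts_norm].
#'
#' @param ts_matrix Gene x tissue numeric matrix of specificity scores.
#' @param genes Gene universe; genes absent from the matrix score 0.
#' @param threshold Specificity cutoff (strict; default 2.5).
#' @param ts_norm Normalizing tissue count (default 32).
#' @return Named numeric vector in [0, 1].
#' @export
tissue_specificity_score <- function(ts_matrix, genes = rownames(ts_matrix),
                                     threshold = 2.5, ts_norm = 32) {
  m <- matrix(0, length(genes), ncol(ts_matrix),
              dimnames = list(genes, colnames(ts_matrix)))
  hit <- intersect(rownames(ts_matrix), genes)
  m[hit, ] <- ts_matrix[hit, , drop = FALSE]
  ts_total <- rowSums(m)
  ts_count <- rowSums(m > threshold)
  (ts_count / ts_norm) * minmax_normalize(ts_total)
}

#' Compute all six layer scores for one disease
#'
#' Aligns every annotation layer to the disease's retained gene universe and
#' returns the gene x layer score matrix (`Gc`, `Gp`, `GT`, `GP`, `GM`,
#' `GTS`). Min-max pools are taken per disease over that universe, since the
#' layers are combined per disease in the final score.
#'
#' @param bundle An `AnnotationBundle` (see [gen_annotation_bundle()] for
#'   the structure; real annotations loaded through the readers fit too).
#' @param deg_table The disease's [build_deg_table()] result (supplies GT).
#' @param genes Gene universe (defaults to the DEG table's genes).
#' @param ts_threshold,ts_norm Passed to [tissue_specificity_score()].
#' @param pli_eps Passed to [pli_score()].
#' @return Numeric matrix, genes x 6 layers, values in [0, 1]; attribute
#'   `disease` carries the disease id.
#' @export
compute_layer_scores <- function(bundle, deg_table, genes = deg_table$gene,
                                 ts_threshold = 2.5, ts_norm = 32,
                                 pli_eps = 1e-12) {
  p <- stats::setNames(deg_table$p_value, deg_table$gene)
  s <- cbind(
    Gc = clinvar_score(bundle$variant_count, genes),
    Gp = pli_score(bundle$pli, genes, eps = pli_eps),
    GT = transcriptome_score(p, genes),
    GP = proteome_score(bundle$degree, genes),
    GM = metabolome_score(bundle$pathways, genes),
    GTS = tissue_specificity_score(bundle$ts_matrix, genes,
                                   threshold = ts_threshold,
                                   ts_norm = ts_norm))
  rownames(s) <- genes
  attr(s, "disease") <- attr(deg_table, "disease")
  s
}
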