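#' Two-sided Wilcoxon rank-sum p-value
#'
#' Masked (`NA`) entries are dropped first. The exact null distribution is
#' used when the smaller group has at most 8 observations and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction is used. If either group is empty after masking, `NaN` is
#' returned with a warning.
#'
#' @param case,control Numeric vectors.
#' @return Two-sided p-value in [0, 1], or `NaN`.
#' @export
wilcoxon_rank_sum <- function(case, control) {
  case <- case[!is.na(case)]
  control <- control[!is.na(control)]
  if (length(case) == 0L || length(control) == 0L) {
    warning("one group empty after masking; returning NaN p-value")
    return(NaN)
  }
  exact <- min(length(case), length(control)) <= 8L &&
    !any(duplicated(c(case, control)))
  suppressWarnings(
    stats::wilcox.test(case, control, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; `NA`/`NaN` inputs are passed through and the
#' remaining values adjusted among themselves.
#'
#' @param pvalues Numeric vector of p-values in [0, 1] (NA allowed).
#' @return Adjusted values, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  out <- pvalues
  ok <- !is.na(pvalues)
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Case/control fold change with a pseudocount
#'
#' `fc = (stat(case) + eps) / (stat(control) + eps)` where `stat` is the
#' median (single datasets, robust to outliers) or the mean (merged
#' profiles, stable across aggregated samples). The pseudocount keeps the
#' ratio finite on min-max-scaled data where group medians are often 0.
#'
#' @param case,control Numeric vectors (NA dropped).
#' @param method `"median"` or `"mean"`.
#' @param eps Pseudocount added to numerator and denominator.
#' @return Strictly positive fold change.
#' @export
fold_change <- function(case, control, method = c("median", "mean"),
                        eps = 1e-8) {
  method <- match.arg(method)
  stat <- if (method == "median") stats::median else mean
  a <- stat(case[!is.na(case)])
  b <- stat(control[!is.na(control)])
  (a + eps) / (b + eps)
}

#' Categorize a gene by fold change and FDR
#'
#' Up-regulated iff `fc > 1` and `fdr <= alpha`; down-regulated iff
#' `fc < 1` and `fdr <= alpha`; everything else (including `fc == 1` and
#' `NaN` statistics) is non-significant. Vectorized.
#'
#' @param fc Positive fold change(s).
#' @param fdr Adjusted p-value(s); `NA` maps to non-significant.
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector in `{"up", "down", "non_significant"}`.
#' @export
categorize <- function(fc, fdr, alpha = 0.05) {
  out <- rep("non_significant", length(fc))
  sig <- !is.na(fdr) & fdr <= alpha & !is.na(fc)
  out[sig & fc > 1] <- "up"
  out[sig & fc < 1] <- "down"
  out
}

#' Differential expression table for a disease profile
#'
#' Per gene: masked-aware case and control vectors, Wilcoxon rank-sum
#' p-value, BH adjustment across genes, fold change with `log2fc =
#' log2(fc)`, and the three-way category. Genes whose test degenerates
#' (a group empty after masking) get `NaN` statistics and the
#' non-significant category.
#'
#' @param profile A [disease_profile()] with >= 1 case and >= 1 control.
#' @param fc_method `"mean"` (merged profiles, the default) or `"median"`
#'   (single datasets).
#' @param alpha FDR threshold for categorization.
#' @param eps Fold-change pseudocount.
#' @return A `deg_table`: data.frame with columns `gene`, `fc`, `log2fc`,
#'   `p_value`, `fdr`, `category`, plus attributes `disease` and
#'   `fc_method`.
#' @export
build_deg_table <- function(profile, fc_method = c("mean", "median"),
                            alpha = 0.05, eps = 1e-8) {
  stopifnot(inherits(profile, "DiseaseProfile"))
  fc_method <- match.arg(fc_method)
  m <- profile$matrix
  if (nrow(m) == 0L) {
    tab <- data.frame(gene = character(0), fc = numeric(0),
                      log2fc = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), category = character(0))
    attr(tab, "disease") <- profile$disease
    attr(tab, "fc_method") <- fc_method
    class(tab) <- c("deg_table", "data.frame")
    return(tab)
  }
  is_case <- profile$labels == "case"
  if (!any(is_case) || all(is_case))
    stop("profile needs at least one case and one control sample")
  case_m <- m[, is_case, drop = FALSE]
  ctrl_m <- m[, !is_case, drop = FALSE]
  n <- nrow(m)
  p <- fc <- numeric(n)
  for (i in seq_len(n)) {
    ca <- case_m[i, ]; co <- ctrl_m[i, ]
    ca <- ca[!is.na(ca)]; co <- co[!is.na(co)]
    if (length(ca) == 0L || length(co) == 0L) {
      p[i] <- NaN; fc[i] <- NaN
    } else {
      p[i] <- wilcoxon_rank_sum(ca, co)
      fc[i] <- fold_change(ca, co, method = fc_method, eps = eps)
    }
  }
  fdr <- bh_adjust(p)
  tab <- data.frame(gene = rownames(m), fc = fc, log2fc = log2(fc),
                    p_value = p, fdr = fdr,
                    category = categorize(fc, fdr, alpha),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(tab, "disease") <- profile$disease
  attr(tab, "fc_method") <- fc_method
  class(tab) <- c("deg_table", "data.frame")
  tab
}

#' Differentially expressed genes of a DEG table
#' @param tab A [build_deg_table()] result.
#' @return Character vector of genes categorized up or down.
#' @export
deg_genes <- function(tab) {
  tab$gene[tab$category %in% c("up", "down")]
}

#' Write a DEG table as TSV
#'
#' Column names mirror the reporting schema (`geneID`, `log2FC`, `p_value`,
#' `p_val_adj`, `category`, optional `cluster`/`label`/`biomarker_type`).
#'
#' @param tab A [build_deg_table()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(tab, path) {
  out <- data.frame(geneID = tab$gene, log2FC = tab$log2fc,
                    p_value = tab$p_value, p_val_adj = tab$fdr,
                    category = tab$category)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
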