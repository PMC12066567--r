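# z-standardize columns; zero-variance columns map to 0
.zscore_cols <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  z <- sweep(m, 2L, mu)
  keep <- sd > 0
  z[, keep] <- sweep(z[, keep, drop = FALSE], 2L, sd[keep], `/`)
  z[, !keep] <- 0
  z
}

#' PCA-derived layer weights
#'
#' Layers are z-standardized and zero-variance layers dropped (their
#' loadings are undefined; they get weight 0). The weight of layer *i* is
#' the absolute loading of that layer on the first principal component,
#' normalized so the weights sum to 1 — PCA1 captures the maximum shared
#' variance, so layers aligned with it dominate the composite. If every
#' layer is zero-variance, uniform weights are returned with a warning.
#'
#' @param layer_scores Gene x layer numeric matrix (>= 2 genes).
#' @return Named non-negative weight vector over the input layers, summing
#'   to 1.
#' @export
pca_layer_weights <- function(layer_scores) {
  stopifnot(is.matrix(layer_scores), nrow(layer_scores) >= 2L)
  sds <- apply(layer_scores, 2L, stats::sd)
  keep <- sds > 0
  w <- stats::setNames(numeric(ncol(layer_scores)), colnames(layer_scores))
  if (!any(keep)) {
    warning("all layers have zero variance; using uniform weights")
    return(w + 1 / length(w))
  }
  z <- scale(layer_scores[, keep, drop = FALSE])
  if (sum(keep) == 1L) {
    w[keep] <- 1
    return(w)
  }
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  load1 <- abs(pc$rotation[, 1L])
  w[keep] <- load1 / sum(load1)
  w
}

#' Final integrated risk score (GF)
#'
#' `GF(g) = sum_i w_i * S_i(g)` where `S_i` is the z-standardized score of
#' layer *i* over the gene universe. Standardization makes GF invariant to
#' affine rescaling of any raw layer.
#'
#' @param layer_scores Gene x layer numeric matrix.
#' @param weights Weight vector from [pca_layer_weights()] (computed from
#'   the scores when omitted).
#' @return Named numeric GF vector over the genes.
#' @export
final_score <- function(layer_scores, weights = NULL) {
  stopifnot(is.matrix(layer_scores))
  if (is.null(weights)) weights <- pca_layer_weights(layer_scores)
  stopifnot(length(weights) == ncol(layer_scores))
  z <- .zscore_cols(layer_scores)
  drop(z %*% weights)
}

#' Assemble the gene x (disease, layer) score matrix
#'
#' One 7-column block per disease, ordered `Gc, Gp, GT, GP, GM, GTS, GF`
#' with column names `"<disease>.<layer>"`; four diseases give the 28-column
#' risk-disease-profile matrix. Rows span the union of the per-disease gene
#' universes; genes absent from a disease carry `NA` in that block.
#'
#' @param layer_scores_list Named list (by disease) of
#'   [compute_layer_scores()] matrices.
#' @param gf_list Named list (by disease) of [final_score()] vectors.
#' @return Numeric matrix with genes as rows.
#' @export
assemble_hirdp <- function(layer_scores_list, gf_list) {
  stopifnot(length(layer_scores_list) >= 1L,
            identical(names(layer_scores_list), names(gf_list)))
  genes <- sort(unique(unlist(lapply(layer_scores_list, rownames),
                              use.names = FALSE)))
  blocks <- lapply(names(layer_scores_list), function(d) {
    s <- cbind(layer_scores_list[[d]], GF = gf_list[[d]])
    out <- matrix(NA_real_, length(genes), ncol(s),
                  dimnames = list(genes, paste(d, colnames(s), sep = ".")))
    out[rownames(s), ] <- s
    out
  })
  do.call(cbind, blocks)
}

#' Presence matrix from DEG tables
#'
#' A gene is "present" in a disease when it is a DEG (up or down) there
#' (`mode = "deg"`), or merely retained in the disease profile
#' (`mode = "profile"`).
#'
#' @param deg_tables Named list (by disease) of [build_deg_table()] results.
#' @param universe Gene universe for the rows (defaults to the union of all
#'   tables' genes; pass the union of raw features to expose genes present
#'   in no disease).
#' @param mode `"deg"` (default) or `"profile"`.
#' @return Logical gene x disease matrix.
#' @export
presence_matrix <- function(deg_tables, universe = NULL,
                            mode = c("deg", "profile")) {
  mode <- match.arg(mode)
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(deg_tables, function(t) t$gene),
                                   use.names = FALSE)))
  pres <- vapply(deg_tables, function(t) {
    hits <- if (mode == "deg") deg_genes(t) else t$gene
    universe %in% hits
  }, logical(length(universe)))
  pres <- matrix(pres, nrow = length(universe),
                 dimnames = list(universe, names(deg_tables)))
  pres
}

#' Group genes by cross-disease presence
#'
#' Presence count 0 -> `Unrelated`, 1 -> `Unique`, 2 -> `Shared-2`,
#' 3 -> `Shared-3`, all diseases -> `Pan-disease`. The labels partition the
#' universe.
#'
#' @param presence Logical gene x disease matrix (see [presence_matrix()]).
#' @return Named factor over the genes with the five group levels.
#' @export
group_genes <- function(presence) {
  stopifnot(is.matrix(presence), is.logical(presence))
  n_dis <- ncol(presence)
  counts <- rowSums(presence)
  lab <- ifelse(counts == 0L, "Unrelated",
         ifelse(counts == 1L, "Unique",
         ifelse(counts == n_dis, "Pan-disease",
                sprintf("Shared-%d", counts))))
  levels <- c("Unrelated", "Unique",
              if (n_dis > 2L) sprintf("Shared-%d", 2:(n_dis - 1L)),
              "Pan-disease")
  stats::setNames(factor(lab, levels = levels), rownames(presence))
}

#' Derive shared and disease-specific biomarker sets
#'
#' The trans set contains genes differentially expressed in both diseases of
#' `trans_pair` but in none of the others:
#' `bio_trans = (DEG_A intersect DEG_B) \ union(other DEG sets)`. Each
#' disease-specific set removes every other disease's DEGs:
#' `bio_X = DEG_X \ union(DEG_Y, Y != X)`.
#'
#' @param deg_sets Named list of DEG gene sets, one per disease.
#' @param trans_pair The two diseases defining the shared set (default
#'   `c("HAPC", "PAH")`, the pair with the closest risk-score patterns in
#'   the four-disease design).
#' @return List of class `BiomarkerSets`: `bio_trans`, one
#'   `bio_<disease>` per disease, `raw_trans` (the pre-subtraction
#'   intersection) and `trans_pair`.
#' @export
derive_biomarker_sets <- function(deg_sets, trans_pair = c("HAPC", "PAH")) {
  stopifnot(is.list(deg_sets), length(deg_sets) >= 2L,
            all(trans_pair %in% names(deg_sets)))
  others <- setdiff(names(deg_sets), trans_pair)
  raw_trans <- intersect(deg_sets[[trans_pair[1L]]], deg_sets[[trans_pair[2L]]])
  bio_trans <- setdiff(raw_trans,
                       unlist(deg_sets[others], use.names = FALSE))
  out <- list(bio_trans = sort(bio_trans), raw_trans = sort(raw_trans),
              trans_pair = trans_pair)
  for (d in names(deg_sets)) {
    rest <- unlist(deg_sets[setdiff(names(deg_sets), d)], use.names = FALSE)
    out[[paste0("bio_", tolower(d))]] <- sort(setdiff(deg_sets[[d]], rest))
  }
  structure(out, class = "BiomarkerSets")
}

#' Attach curated biomarker-type labels
#'
#' Biomarker types (direct, intermediate crucial, potential minor-effect)
#' come from literature curation and are never inferred; this merely joins a
#' curation table onto a gene vector.
#'
#' @param genes Character vector of gene symbols.
#' @param curation Data.frame with columns `gene` and `biomarker_type`, or
#'   `NULL`.
#' @return Named character vector; genes without curation are
#'   `"unclassified"`.
#' @export
biomarker_types <- function(genes, curation = NULL) {
  out <- stats::setNames(rep("unclassified", length(genes)), genes)
  if (!is.null(curation)) {
    hit <- intersect(toupper(curation$gene), genes)
    out[hit] <- curation$biomarker_type[match(hit, toupper(curation$gene))]
  }
  out
}

#' Cross-disease comparison of final scores
#'
#' Kruskal-Wallis omnibus test of GF across diseases, followed by pairwise
#' two-sided Wilcoxon rank-sum tests with BH adjustment. Typically run on
#' the genes scored in all diseases (complete rows).
#'
#' @param gf Gene x disease numeric matrix of final scores (NA rows for a
#'   disease are dropped within that disease).
#' @return List with `omnibus_p`, `pairwise` (symmetric disease x disease
#'   matrix of BH-adjusted p-values, unit diagonal) and `n_genes` per
#'   disease.
#' @export
gf_group_tests <- function(gf) {
  stopifnot(is.matrix(gf), ncol(gf) >= 2L)
  vals <- as.vector(gf)
  grp <- factor(rep(colnames(gf), each = nrow(gf)), levels = colnames(gf))
  ok <- !is.na(vals)
  vals <- vals[ok]; grp <- droplevels(grp[ok])
  if (nlevels(grp) < 2L || min(table(grp)) < 2L) {
    warning("degenerate groups; returning NaN test results")
    return(list(omnibus_p = NaN, pairwise = NULL,
                n_genes = table(grp)))
  }
  kw <- stats::kruskal.test(vals, grp)
  pw <- stats::pairwise.wilcox.test(vals, grp, p.adjust.method = "BH",
                                    exact = FALSE)$p.value
  dis <- levels(grp)
  full <- matrix(1, length(dis), length(dis), dimnames = list(dis, dis))
  for (a in rownames(pw)) for (b in colnames(pw))
    if (!is.na(pw[a, b])) full[a, b] <- full[b, a] <- pw[a, b]
  list(omnibus_p = kw$p.value, pairwise = full,
       n_genes = table(grp))
}

#' Cluster genes on their cross-disease final scores
#'
#' Hierarchical clustering uses Euclidean distance with Ward's ward.D2
#' linkage (deterministic); k-means uses a fixed seed. Missing entries are
#' imputed with column means for the distance computation only.
#'
#' @param gf Gene x disease numeric matrix (typically genes present in >= 3
#'   diseases).
#' @param method `"hierarchical"` or `"kmeans"`.
#' @param k Number of clusters (default 4, the number of diseases).
#' @param seed RNG seed for k-means (default 0).
#' @return List with `labels` (named cluster assignment), `method`, and for
#'   hierarchical clustering `hclust` (the gene tree) and `disease_order`
#'   (column order of the disease dendrogram, ward.D2 on the transposed
#'   matrix).
#' @export
cluster_gf <- function(gf, method = c("hierarchical", "kmeans"), k = 4L,
                       seed = 0L) {
  method <- match.arg(method)
  stopifnot(is.matrix(gf), nrow(gf) >= 1L)
  if (k > nrow(gf)) stop("k exceeds the number of genes")
  x <- gf
  for (j in seq_len(ncol(x))) {
    mu <- mean(x[, j], na.rm = TRUE)
    x[is.na(x[, j]), j] <- mu
  }
  if (nrow(x) == 1L)
    return(list(labels = stats::setNames(1L, rownames(x)), method = method))
  if (method == "hierarchical") {
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    labels <- stats::cutree(hc, k = min(k, nrow(x)))
    dis_hc <- if (ncol(x) >= 2L)
      stats::hclust(stats::dist(t(x)), method = "ward.D2") else NULL
    list(labels = labels, method = method, hclust = hc,
         disease_order = if (!is.null(dis_hc)) colnames(x)[dis_hc$order]
                         else colnames(x))
  } else {
    set.seed(seed)
    km <- stats::kmeans(x, centers = k, nstart = 10L)
    list(labels = stats::setNames(km$cluster, rownames(x)), method = method,
         centers = km$centers)
  }
}

#' Hypergeometric over-representation test
#'
#' For each gene set, the one-sided hypergeometric tail probability of
#' observing at least the seen overlap between the query and the set within
#' the universe; BH adjustment across sets; rows with `p <= alpha` are
#' flagged significant.
#'
#' @param query Gene set of interest (must be a subset of `universe`).
#' @param universe Background gene universe.
#' @param gene_sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param alpha Significance flag threshold (default 0.05).
#' @return Data.frame (`set_id`, `set_size`, `overlap`, `p`, `fdr`,
#'   `significant`) sorted by p-value.
#' @export
ora_hypergeometric <- function(query, universe, gene_sets, alpha = 0.05) {
  query <- unique(toupper(query)); universe <- unique(toupper(universe))
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  if (length(query) == 0L)
    return(data.frame(set_id = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  n_uni <- length(universe)
  rows <- lapply(names(gene_sets), function(s) {
    set <- intersect(unique(toupper(gene_sets[[s]])), universe)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1L, length(set), n_uni - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set_id = s, set_size = length(set), overlap = k, p = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p <= alpha
  out[order(out$p), , drop = FALSE]
}
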