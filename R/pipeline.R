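#' Pipeline configuration
#'
#' Consolidates every threshold of the analysis in one validated object.
#' A YAML file with the same field names can be loaded with
#' [load_pipeline_config()]; unknown fields are rejected.
#'
#' @param manifest Path to the dataset manifest TSV.
#' @param variant,pli,ppi,gmt,ts_matrix Paths to the annotation inputs
#'   (per-gene variant counts, pLI values, PPI degree/edge list, pathway
#'   GMT, gene x tissue score matrix).
#' @param curation Optional path to a biomarker-type curation TSV (columns
#'   `gene`, `biomarker_type`).
#' @param max_zero_frac,outlier_lo,outlier_hi,alpha,ts_threshold,ts_norm,fc_eps,pli_eps
#'   Analysis thresholds; the defaults are the study's settings.
#' @param presence_mode `"deg"` (a gene is present in a disease when
#'   differentially expressed there) or `"profile"` (present when retained
#'   in the profile).
#' @param trans_pair Two diseases defining the shared biomarker set.
#' @param kmeans_k Number of k-means clusters (default 4).
#' @param seed RNG seed for the stochastic steps (k-means).
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(manifest, variant = NULL, pli = NULL, ppi = NULL,
                            gmt = NULL, ts_matrix = NULL, curation = NULL,
                            max_zero_frac = 0.75, outlier_lo = 0.10,
                            outlier_hi = 0.90, alpha = 0.05,
                            ts_threshold = 2.5, ts_norm = 32,
                            fc_eps = 1e-8, pli_eps = 1e-12,
                            presence_mode = c("deg", "profile"),
                            trans_pair = c("HAPC", "PAH"),
                            kmeans_k = 4L, seed = 1L) {
  presence_mode <- match.arg(presence_mode)
  .assert_fraction(max_zero_frac, "max_zero_frac")
  .assert_fraction(outlier_lo, "outlier_lo")
  .assert_fraction(outlier_hi, "outlier_hi")
  .assert_fraction(alpha, "alpha")
  if (outlier_lo >= outlier_hi) stop("outlier_lo must be below outlier_hi")
  structure(
    list(manifest = manifest, variant = variant, pli = pli, ppi = ppi,
         gmt = gmt, ts_matrix = ts_matrix, curation = curation,
         max_zero_frac = max_zero_frac, outlier_lo = outlier_lo,
         outlier_hi = outlier_hi, alpha = alpha,
         ts_threshold = ts_threshold, ts_norm = ts_norm,
         fc_eps = fc_eps, pli_eps = pli_eps,
         presence_mode = presence_mode, trans_pair = trans_pair,
         kmeans_k = as.integer(kmeans_k), seed = as.integer(seed)),
    class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' Field names mirror the [pipeline_config()] arguments; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `PipelineConfig`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  dir <- dirname(path)
  for (f in c("manifest", "variant", "pli", "ppi", "gmt", "ts_matrix",
              "curation")) {
    if (!is.null(raw[[f]]) && !file.exists(raw[[f]]))
      raw[[f]] <- file.path(dir, raw[[f]])
  }
  do.call(pipeline_config, raw)
}

#' Summarize a dataset manifest
#'
#' Column sums of cases and controls per disease and overall.
#'
#' @param manifest A manifest data.frame ([read_manifest()]) or a path.
#' @return List with `per_disease` (data.frame: disease, n_datasets,
#'   n_cases, n_controls), `n_datasets`, `n_cases`, `n_controls`.
#' @export
summarize_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(manifest) == 0L)
    return(list(per_disease = data.frame(disease = character(0),
                                         n_datasets = integer(0),
                                         n_cases = integer(0),
                                         n_controls = integer(0)),
                n_datasets = 0L, n_cases = 0L, n_controls = 0L))
  per <- do.call(rbind, lapply(split(manifest, manifest$disease), function(d)
    data.frame(disease = d$disease[1L], n_datasets = nrow(d),
               n_cases = sum(d$n_cases), n_controls = sum(d$n_controls))))
  rownames(per) <- NULL
  list(per_disease = per, n_datasets = nrow(manifest),
       n_cases = sum(manifest$n_cases), n_controls = sum(manifest$n_controls))
}

# load annotation inputs named in the config into an AnnotationBundle-shaped
# list; absent sources yield empty layers that score 0
.load_bundle <- function(config, genes) {
  variant <- if (!is.null(config$variant)) read_annotation_tsv(config$variant)
             else stats::setNames(numeric(0), character(0))
  pli <- if (!is.null(config$pli)) read_annotation_tsv(config$pli)
         else stats::setNames(numeric(0), character(0))
  degree <- if (!is.null(config$ppi)) read_ppi_degrees(config$ppi)
            else stats::setNames(numeric(0), character(0))
  pathways <- if (!is.null(config$gmt)) .invert_gmt(read_gmt(config$gmt), genes)
              else stats::setNames(rep(list(character(0)), length(genes)), genes)
  ts <- if (!is.null(config$ts_matrix)) read_ts_matrix(config$ts_matrix)
        else matrix(0, 0, 1, dimnames = list(NULL, "T01"))
  structure(list(variant_count = variant, pli = pli, degree = degree,
                 pathways = pathways, ts_matrix = ts,
                 n_tissues_norm = config$ts_norm),
            class = "AnnotationBundle")
}

#' Run the full cross-omics risk-assessment pipeline
#'
#' Reads the manifest, builds one preprocessed profile and DEG table per
#' disease (mean-based fold change, as appropriate for merged profiles),
#' scores every retained gene on the six evidence layers, derives
#' PCA-weighted final scores, assembles the gene x (disease, layer) score
#' matrix, groups genes by cross-disease presence, derives the shared and
#' disease-specific biomarker sets, compares final scores across diseases,
#' clusters genes present in at least three diseases, and (when a GMT is
#' supplied) runs over-representation tests for the shared biomarker set.
#' All artifacts are written under `out_dir`; the log records every
#' threshold applied and the per-stage feature counts. Deterministic under
#' `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results: `profiles`,
#'   `deg_tables`, `layer_scores`, `weights`, `gf`, `hirdp`, `presence`,
#'   `groups`, `biomarkers`, `gf_tests`, `clusters`, `ora`, `summary`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!file.exists(config$manifest))
    stop("missing input file: ", config$manifest)
  manifest <- read_manifest(config$manifest)
  datasets <- load_manifest_datasets(manifest)
  diseases <- unique(manifest$disease)

  log_lines <- c(sprintf("hirisk run: %d datasets, %d diseases",
                         nrow(manifest), length(diseases)),
                 sprintf("thresholds: max_zero_frac=%g outlier=[%g,%g] alpha=%g ts_threshold=%g ts_norm=%d fc_eps=%g pli_eps=%g presence_mode=%s kmeans_k=%d seed=%d",
                         config$max_zero_frac, config$outlier_lo,
                         config$outlier_hi, config$alpha, config$ts_threshold,
                         config$ts_norm, config$fc_eps, config$pli_eps,
                         config$presence_mode, config$kmeans_k, config$seed))

  profiles <- list(); deg_tables <- list()
  universe_raw <- character(0)
  for (d in diseases) {
    ds <- datasets[manifest$dataset_id[manifest$disease == d]]
    universe_raw <- union(universe_raw,
                          unlist(lapply(ds, function(x) rownames(x$matrix)),
                                 use.names = FALSE))
    prof <- build_disease_profile(ds, max_zero_frac = config$max_zero_frac,
                                  lo = config$outlier_lo,
                                  hi = config$outlier_hi)
    deg <- build_deg_table(prof, fc_method = "mean", alpha = config$alpha,
                           eps = config$fc_eps)
    profiles[[d]] <- prof
    deg_tables[[d]] <- deg
    write_expression_tsv(prof$matrix,
                         file.path(out_dir, sprintf("profile_%s.tsv", d)))
    jsonlite::write_json(
      list(disease = d, batch = as.list(prof$batch), log = prof$log),
      file.path(out_dir, sprintf("profile_%s.json", d)), auto_unbox = TRUE)
    write_deg_table(deg, file.path(out_dir, sprintf("deg_%s.tsv", d)))
    log_lines <- c(log_lines,
                   sprintf("%s: raw features %s; filtered %s; merged %d; DEGs %d",
                           d, paste(prof$log$n_features_raw, collapse = "/"),
                           paste(prof$log$n_features_filtered, collapse = "/"),
                           nrow(prof$matrix), length(deg_genes(deg))))
  }

  layer_scores <- list(); weights <- list(); gf <- list()
  for (d in diseases) {
    bundle <- .load_bundle(config, deg_tables[[d]]$gene)
    s <- compute_layer_scores(bundle, deg_tables[[d]],
                              ts_threshold = config$ts_threshold,
                              ts_norm = config$ts_norm,
                              pli_eps = config$pli_eps)
    w <- pca_layer_weights(s)
    layer_scores[[d]] <- s
    weights[[d]] <- w
    gf[[d]] <- final_score(s, w)
  }
  hirdp <- assemble_hirdp(layer_scores, gf)
  write_expression_tsv(hirdp, file.path(out_dir, "hirdp_matrix.tsv"))

  presence <- presence_matrix(deg_tables, universe = sort(universe_raw),
                              mode = config$presence_mode)
  groups <- group_genes(presence)
  utils::write.table(
    data.frame(gene = names(groups), group = as.character(groups),
               n_diseases = rowSums(presence)),
    file.path(out_dir, "gene_groups.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  deg_sets <- lapply(deg_tables, deg_genes)
  biomarkers <- NULL
  if (all(config$trans_pair %in% diseases)) {
    biomarkers <- derive_biomarker_sets(deg_sets,
                                        trans_pair = config$trans_pair)
    curation <- if (!is.null(config$curation))
      utils::read.delim(config$curation, stringsAsFactors = FALSE) else NULL
    rows <- list()
    for (nm in grep("^bio_", names(biomarkers), value = TRUE)) {
      gs <- biomarkers[[nm]]
      if (!length(gs)) next
      rows[[nm]] <- data.frame(
        geneID = gs, cluster = nm,
        label = vapply(gs, function(g) {
          for (d in diseases) {
            hit <- deg_tables[[d]]$category[deg_tables[[d]]$gene == g]
            if (length(hit) && hit %in% c("up", "down"))
              return(if (hit == "up") "Sigup" else "Sigdown")
          }
          "Sigup"
        }, character(1L)),
        biomarker_type = unname(biomarker_types(gs, curation)))
    }
    if (length(rows))
      utils::write.table(do.call(rbind, rows),
                         file.path(out_dir, "biomarker_sets.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  gf_cols <- grep("\\.GF$", colnames(hirdp))
  gf_mat <- hirdp[, gf_cols, drop = FALSE]
  colnames(gf_mat) <- sub("\\.GF$", "", colnames(gf_mat))
  pan <- rownames(gf_mat)[rowSums(!is.na(gf_mat)) == ncol(gf_mat)]
  gf_tests <- if (length(pan) >= 4L && ncol(gf_mat) >= 2L)
    gf_group_tests(gf_mat[pan, , drop = FALSE]) else NULL

  in3 <- rownames(gf_mat)[rowSums(!is.na(gf_mat)) >= min(3L, ncol(gf_mat))]
  clusters <- NULL
  if (length(in3) >= config$kmeans_k) {
    clusters <- list(
      hierarchical = cluster_gf(gf_mat[in3, , drop = FALSE], "hierarchical",
                                k = config$kmeans_k),
      kmeans = cluster_gf(gf_mat[in3, , drop = FALSE], "kmeans",
                          k = config$kmeans_k, seed = config$seed))
  }

  ora <- NULL
  if (!is.null(config$gmt) && !is.null(biomarkers) &&
      length(biomarkers$bio_trans)) {
    ora <- ora_hypergeometric(intersect(biomarkers$bio_trans, universe_raw),
                              universe_raw, read_gmt(config$gmt),
                              alpha = config$alpha)
  }

  summary <- summarize_manifest(manifest)
  report <- list(
    summary = summary[c("n_datasets", "n_cases", "n_controls")],
    n_hirdp_columns = ncol(hirdp),
    group_sizes = as.list(table(groups)),
    biomarker_sizes = if (!is.null(biomarkers))
      lapply(biomarkers[grep("^bio_", names(biomarkers))], length) else NULL,
    gf_omnibus_p = if (!is.null(gf_tests)) gf_tests$omnibus_p else NULL,
    gf_pairwise = if (!is.null(gf_tests))
      as.data.frame(gf_tests$pairwise) else NULL)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(ora))
    utils::write.table(ora, file.path(out_dir, "ora_bio_trans.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(profiles = profiles, deg_tables = deg_tables,
                 layer_scores = layer_scores, weights = weights, gf = gf,
                 hirdp = hirdp, presence = presence, groups = groups,
                 biomarkers = biomarkers, gf_tests = gf_tests,
                 clusters = clusters, ora = ora, summary = summary))
}

#' Path of the packaged study manifest
#'
#' The 15-dataset overview of the four-disease H-I study (disease, GEO
#' dataset id, case and control counts) shipped as a package fixture for
#' [summarize_manifest()].
#'
#' @return File path of the TSV inside the installed package.
#' @export
study_manifest_path <- function() {
  system.file("extdata", "table1_manifest.tsv", package = "hirisk",
              mustWork = TRUE)
}
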