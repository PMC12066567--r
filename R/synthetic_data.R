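#' Simulation configuration for synthetic H-I study fixtures
#'
#' Defines the conditions the generator emulates: several diseases measured
#' by several heterogeneous datasets each, log-normal expression intensities,
#' planted shared and disease-specific differentially expressed genes,
#' per-dataset batch distortion, and missingness encoded as zeros.
#'
#' @param n_diseases Number of diseases (default 4, matching the H-I study
#'   design of PAH, HAPC, IS, PE).
#' @param datasets_per_disease Datasets generated per disease.
#' @param n_genes Size of the gene universe.
#' @param cases_per_dataset,controls_per_dataset Samples per arm per dataset.
#' @param frac_shared_deg Fraction of the gene universe planted as DEGs
#'   shared between disease pairs (split evenly over all pairs).
#' @param frac_specific_deg Fraction planted as disease-specific DEGs
#'   (split evenly over diseases, disjoint from the shared pool).
#' @param effect_size Additive case-vs-control shift on the log-expression
#'   scale, in units of the unit residual SD (so 2 means 2 pooled SDs).
#' @param batch_shift_sd SD of the per-gene, per-dataset additive shift on
#'   the log scale.
#' @param batch_scale_sd SD (log scale) of the per-dataset multiplicative
#'   distortion applied to log-expression.
#' @param missing_rate Fraction of entries zeroed out as "missing".
#' @param gene_dropout_frac Fraction of genes absent from any single dataset,
#'   emulating heterogeneous feature counts across platforms.
#' @param n_tissues Number of tissues in the specificity matrix (default 32).
#' @param seed Integer master seed; all generator randomness derives from it.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_diseases = 4L, datasets_per_disease = 2L,
                              n_genes = 2000L, cases_per_dataset = 25L,
                              controls_per_dataset = 25L,
                              frac_shared_deg = 0.05, frac_specific_deg = 0.05,
                              effect_size = 2, batch_shift_sd = 0.5,
                              batch_scale_sd = 0.1, missing_rate = 0.05,
                              gene_dropout_frac = 0.03,
                              n_tissues = 32L, seed = 1L) {
  .assert_count(n_diseases, "n_diseases")
  .assert_count(datasets_per_disease, "datasets_per_disease")
  .assert_count(n_genes, "n_genes")
  .assert_count(cases_per_dataset, "cases_per_dataset")
  .assert_count(controls_per_dataset, "controls_per_dataset")
  .assert_count(n_tissues, "n_tissues")
  .assert_fraction(frac_shared_deg, "frac_shared_deg")
  .assert_fraction(frac_specific_deg, "frac_specific_deg")
  .assert_fraction(missing_rate, "missing_rate")
  .assert_fraction(gene_dropout_frac, "gene_dropout_frac")
  if (frac_shared_deg + frac_specific_deg > 1)
    stop("frac_shared_deg + frac_specific_deg must not exceed 1")
  if (!is.numeric(effect_size) || effect_size < 0)
    stop("effect_size must be a non-negative real")
  if (batch_shift_sd < 0 || batch_scale_sd < 0)
    stop("batch SDs must be non-negative")
  structure(
    list(n_diseases = as.integer(n_diseases),
         datasets_per_disease = as.integer(datasets_per_disease),
         n_genes = as.integer(n_genes),
         cases_per_dataset = as.integer(cases_per_dataset),
         controls_per_dataset = as.integer(controls_per_dataset),
         frac_shared_deg = frac_shared_deg,
         frac_specific_deg = frac_specific_deg,
         effect_size = effect_size,
         batch_shift_sd = batch_shift_sd,
         batch_scale_sd = batch_scale_sd,
         missing_rate = missing_rate,
         gene_dropout_frac = gene_dropout_frac,
         n_tissues = as.integer(n_tissues),
         seed = as.integer(seed)),
    class = "SimulationConfig")
}

#' Disease identifiers used by a simulation configuration
#'
#' The first four names mirror the H-I study diseases; beyond four, generic
#' ids are appended.
#'
#' @param cfg A [simulation_config()] object.
#' @return Character vector of length `cfg$n_diseases`.
#' @export
sim_diseases <- function(cfg) {
  base <- c("PAH", "HAPC", "IS", "PE")
  n <- cfg$n_diseases
  if (n <= 4L) base[seq_len(n)] else c(base, sprintf("D%02d", 5:n))
}

#' Ground truth of planted effects
#'
#' Draws the planted shared (per disease pair) and disease-specific DEG sets,
#' their directions, and the high-evidence gene set that the annotation
#' generator boosts across layers. All sets are disjoint by construction and
#' deterministic under `cfg$seed`.
#'
#' @param cfg A [simulation_config()] object.
#' @return A list of class `GroundTruth` with elements `genes`,
#'   `shared_deg_genes` (named by "A|B" pair), `specific_deg_genes` (named by
#'   disease), `deg_genes` (per-disease union of shared and specific),
#'   `deg_direction` ("up"/"down" per planted gene) and
#'   `high_evidence_genes`.
#' @export
make_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(.stream_seed(cfg$seed, "truth"))
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  dis <- sim_diseases(cfg)
  pairs <- if (length(dis) >= 2L) utils::combn(dis, 2L, simplify = FALSE) else list()
  n_shared_each <- if (length(pairs))
    floor(cfg$frac_shared_deg * cfg$n_genes / length(pairs)) else 0L
  n_spec_each <- floor(cfg$frac_specific_deg * cfg$n_genes / length(dis))
  need <- n_shared_each * length(pairs) + n_spec_each * length(dis)
  pool <- sample(genes, need)
  shared <- list(); i <- 0L
  for (p in pairs) {
    shared[[paste(p, collapse = "|")]] <- pool[seq_len(n_shared_each) + i]
    i <- i + n_shared_each
  }
  specific <- list()
  for (d in dis) {
    specific[[d]] <- pool[seq_len(n_spec_each) + i]
    i <- i + n_spec_each
  }
  deg_genes <- lapply(stats::setNames(dis, dis), function(d) {
    sh <- unlist(shared[vapply(pairs, function(p) d %in% p, logical(1L))],
                 use.names = FALSE)
    sort(unique(c(sh, specific[[d]])))
  })
  planted <- pool
  direction <- stats::setNames(sample(c("up", "down"), length(planted),
                                      replace = TRUE), planted)
  n_he <- min(length(planted), max(10L, round(0.02 * cfg$n_genes)))
  high_evidence <- sort(sample(planted, n_he))
  structure(
    list(genes = genes, shared_deg_genes = shared,
         specific_deg_genes = specific, deg_genes = deg_genes,
         deg_direction = direction, high_evidence_genes = high_evidence),
    class = "GroundTruth")
}

#' Generate one synthetic expression dataset
#'
#' Log-expression is drawn as `gene baseline + batch shift + planted effect +
#' N(0, 1) noise`, scaled by a dataset-level multiplicative factor, then
#' exponentiated to a non-negative intensity scale. A `missing_rate` fraction
#' of entries is zeroed (the true missing positions are kept in
#' `missing_mask`), and a `gene_dropout_frac` subset of genes is absent from
#' the dataset altogether. Output is deterministic under
#' `(cfg$seed, disease, dataset_index)`, and generating one dataset never
#' perturbs another.
#'
#' @param cfg A [simulation_config()] object.
#' @param disease Disease id (one of [sim_diseases()]).
#' @param dataset_index Index of the dataset within the disease (1-based).
#' @param truth Optional precomputed [make_ground_truth()] result.
#' @return An [expression_dataset()] object.
#' @export
gen_expression_dataset <- function(cfg, disease, dataset_index, truth = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  .assert_count(dataset_index, "dataset_index")
  if (is.null(truth)) truth <- make_ground_truth(cfg)
  if (!disease %in% sim_diseases(cfg))
    stop(sprintf("unknown disease '%s'", disease))

  # gene baselines shared across all datasets (fixed by the master seed)
  set.seed(.stream_seed(cfg$seed, "baselines"))
  mu <- stats::rnorm(cfg$n_genes, mean = 4, sd = 1)
  names(mu) <- truth$genes

  set.seed(.stream_seed(cfg$seed, "dataset", disease, dataset_index))
  n_case <- cfg$cases_per_dataset
  n_ctrl <- cfg$controls_per_dataset
  n <- n_case + n_ctrl
  dataset_id <- sprintf("%s_DS%d", disease, dataset_index)
  samples <- sprintf("%s_S%03d", dataset_id, seq_len(n))
  labels <- stats::setNames(rep(c("case", "control"), c(n_case, n_ctrl)), samples)

  eff <- stats::setNames(numeric(cfg$n_genes), truth$genes)
  planted <- truth$deg_genes[[disease]]
  eff[planted] <- cfg$effect_size *
    ifelse(truth$deg_direction[planted] == "up", 1, -1)

  shift <- stats::rnorm(cfg$n_genes, 0, cfg$batch_shift_sd)
  scale_fac <- exp(stats::rnorm(1L, 0, cfg$batch_scale_sd))
  logx <- matrix(mu + shift, cfg$n_genes, n) +
    outer(eff, as.numeric(labels == "case")) +
    matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n)
  m <- exp(scale_fac * logx)
  dimnames(m) <- list(truth$genes, samples)

  miss <- matrix(stats::runif(length(m)) < cfg$missing_rate,
                 nrow(m), ncol(m), dimnames = dimnames(m))
  m[miss] <- 0

  if (cfg$gene_dropout_frac > 0) {
    n_drop <- floor(cfg$gene_dropout_frac * cfg$n_genes)
    if (n_drop > 0L) {
      drop <- sample(cfg$n_genes, n_drop)
      m <- m[-drop, , drop = FALSE]
      miss <- miss[-drop, , drop = FALSE]
    }
  }
  expression_dataset(m, labels, dataset_id, disease, missing_mask = miss)
}

#' Generate the annotation bundle matched to a ground truth
#'
#' Produces variant counts (negative binomial background, inflated to at
#' least the background 90th percentile for high-evidence genes), pLI values
#' in [0, 1], heavy-tailed interaction-network degrees, pathway memberships
#' with one globally dominant pathway, and a gene x tissue specificity matrix
#' in which a minority of genes exceed 2.5 in at least one tissue. The first
#' background gene is stripped of pathway annotations so the zero-membership
#' path is always exercised.
#'
#' @param cfg A [simulation_config()] object.
#' @param truth A [make_ground_truth()] result.
#' @return A list of class `AnnotationBundle` with elements `variant_count`,
#'   `pli`, `degree` (named numeric vectors), `pathways` (named list of
#'   character vectors), `ts_matrix` (gene x tissue matrix) and
#'   `n_tissues_norm`.
#' @export
gen_annotation_bundle <- function(cfg, truth) {
  stopifnot(inherits(cfg, "SimulationConfig"), inherits(truth, "GroundTruth"))
  set.seed(.stream_seed(cfg$seed, "annotation"))
  genes <- truth$genes
  n <- length(genes)
  he <- genes %in% truth$high_evidence_genes

  variant <- stats::rnbinom(n, size = 1, mu = 8)
  q90 <- stats::quantile(variant[!he], 0.9, names = FALSE)
  variant[he] <- ceiling(q90) + stats::rpois(sum(he), 15)
  variant <- stats::setNames(as.numeric(variant), genes)

  pli <- stats::rbeta(n, 0.3, 0.3)
  pli[he] <- stats::runif(sum(he), 0.9, 1)
  pli <- stats::setNames(pmin(pmax(pli, 0), 1), genes)

  degree <- round(stats::rlnorm(n, meanlog = log(5), sdlog = 1.2))
  degree[he] <- degree[he] + round(stats::rlnorm(sum(he), meanlog = log(60),
                                                 sdlog = 0.5))
  degree <- stats::setNames(as.numeric(degree), genes)

  pw_ids <- sprintf("PW%02d", seq_len(25L))
  dominant <- pw_ids[1L]
  pathways <- lapply(seq_len(n), function(i) {
    pws <- character(0)
    if (he[i] || stats::runif(1) < 0.3) pws <- dominant
    k <- stats::rbinom(1L, 2L, 0.4)
    if (k > 0L) pws <- union(pws, sample(pw_ids[-1L], k))
    sort(pws)
  })
  names(pathways) <- genes
  first_bg <- which(!he)[1L]
  pathways[[first_bg]] <- character(0)

  ts <- matrix(abs(stats::rnorm(n * cfg$n_tissues, 0, 1)),
               n, cfg$n_tissues,
               dimnames = list(genes, sprintf("T%02d", seq_len(cfg$n_tissues))))
  spec_genes <- which(he | stats::runif(n) < 0.08)
  for (i in spec_genes) {
    k <- sample(1:4, 1L)
    ts[i, sample(cfg$n_tissues, k)] <- stats::runif(k, 3, 6)
  }

  structure(
    list(variant_count = variant, pli = pli, degree = degree,
         pathways = pathways, ts_matrix = ts,
         n_tissues_norm = cfg$n_tissues),
    class = "AnnotationBundle")
}

#' Generate a full synthetic study
#'
#' Convenience wrapper: ground truth, every dataset of every disease, and the
#' matched annotation bundle.
#'
#' @param cfg A [simulation_config()] object.
#' @return A list with elements `cfg`, `truth`, `datasets` (named list of
#'   [expression_dataset()] objects) and `bundle`.
#' @export
simulate_study <- function(cfg) {
  truth <- make_ground_truth(cfg)
  datasets <- list()
  for (d in sim_diseases(cfg)) {
    for (i in seq_len(cfg$datasets_per_disease)) {
      ds <- gen_expression_dataset(cfg, d, i, truth)
      datasets[[ds$dataset_id]] <- ds
    }
  }
  list(cfg = cfg, truth = truth, datasets = datasets,
       bundle = gen_annotation_bundle(cfg, truth))
}
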