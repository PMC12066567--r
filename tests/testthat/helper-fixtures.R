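# shared fixture builders for the test suite

# tiny hand-sized dataset with explicit values
toy_dataset <- function(m, labels = NULL, id = "DS1", disease = "PAH") {
  if (is.null(labels)) {
    n <- ncol(m)
    labels <- stats::setNames(rep(c("case", "control"), length.out = n),
                              colnames(m))
  }
  expression_dataset(m, labels, id, disease)
}

toy_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# small simulated study reused across test files (cheap: 300 genes)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_study(simulation_config(n_genes = 300, seed = 42))
    cache
  }
})

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n+m, n) assignments of the pooled ranks (no ties assumed)
enumerate_wilcoxon_p <- function(case, control) {
  pooled <- c(case, control)
  stopifnot(!any(duplicated(pooled)))
  n <- length(case)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2   # Mann-Whitney U
  combos <- utils::combn(length(pooled), n)
  u_all <- apply(combos, 2L, function(idx)
    sum(rank(pooled)[idx]) - n * (n + 1) / 2)
  mu <- n * length(control) / 2
  # two-sided: double the smaller tail (with point mass), capped at 1
  p <- 2 * min(mean(u_all <= w_obs), mean(u_all >= w_obs))
  min(p, 1)
}

# brute-force BH step-up: p_(i) * m / i, cumulative min from the tail
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# mean silhouette width of batch labels on sample profiles (euclidean)
batch_silhouette <- function(m, batch) {
  d <- dist(t(m))
  mean(cluster::silhouette(as.integer(factor(batch)), d)[, "sil_width"])
}
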