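test_that("feature filter removes genes strictly above the zero threshold", {
  m <- toy_matrix(c(0, 0, 0, 5,    # 3/4 zeros: exactly 0.75, retained
                    0, 0, 0, 0,    # 4/4 zeros: removed
                    1, 2, 3, 4),   # dense: retained
                  c("A", "B", "C"), sprintf("S%d", 1:4))
  ds <- filter_features(toy_dataset(m))
  expect_identical(rownames(ds$matrix), c("A", "C"))
  expect_equal(ncol(ds$matrix), 4)
  # dense matrix unchanged; all-zero matrix fully removed
  dense <- toy_dataset(toy_matrix(1:8, c("A", "B"), sprintf("S%d", 1:4)))
  expect_identical(filter_features(dense)$matrix, dense$matrix)
  zeros <- toy_dataset(toy_matrix(rep(0, 8), c("A", "B"), sprintf("S%d", 1:4)))
  expect_equal(nrow(filter_features(zeros)$matrix), 0)
})

test_that("zero imputation touches only missing cells", {
  m <- toy_matrix(c(1, NA, 3, 4, 5, 6), c("A", "B"), sprintf("S%d", 1:3))
  ds <- impute_missing(toy_dataset(m))
  expect_equal(ds$matrix["A", 2], 0)
  expect_equal(ds$matrix["A", c(1, 3)], c(S1 = 1, S3 = 3))
  expect_equal(ds$matrix["B", ], c(S1 = 4, S2 = 5, S3 = 6))
  clean <- toy_dataset(toy_matrix(1:6, c("A", "B"), sprintf("S%d", 1:3)))
  expect_identical(impute_missing(clean)$matrix, clean$matrix)
})

test_that("min-max normalization follows the closed form and is idempotent", {
  expect_equal(minmax_normalize(c(1, 2, 3)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(5, 5, 5)), c(0, 0, 0))
  # idempotent on already-normalized non-constant vectors
  for (i in 1:20) {
    v <- minmax_normalize(rnorm(10))
    expect_equal(minmax_normalize(v), v)
  }
  # NA positions are preserved
  expect_equal(minmax_normalize(c(1, NA, 3)), c(0, NA, 1))
})

test_that("merging intersects genes and row-normalizes across samples", {
  d1 <- toy_dataset(toy_matrix(c(1, 2, 3, 4, 9, 9), c("A", "B", "C"),
                               c("X1", "X2")), id = "DS1")
  d2 <- toy_dataset(toy_matrix(c(5, 6, 7, 8), c("A", "B"),
                               c("Y1", "Y2")), id = "DS2")
  prof <- merge_by_gene(list(d1, d2))
  expect_s3_class(prof, "DiseaseProfile")
  expect_identical(rownames(prof$matrix), c("A", "B"))
  expect_equal(unname(prof$batch),
               c("DS1", "DS1", "DS2", "DS2"))
  # non-constant rows span [0, 1] after normalization
  expect_equal(unname(apply(prof$matrix, 1, range)),
               matrix(c(0, 1, 0, 1), 2))
  # empty intersection is an explicit error
  d3 <- toy_dataset(toy_matrix(1:2, "Z", c("W1", "W2")), id = "DS3")
  expect_error(merge_by_gene(list(d1, d3)), "empty gene intersection")
  # single dataset profile is just the row-normalized dataset
  solo <- merge_by_gene(list(d1))
  expect_equal(solo$matrix, hirisk:::.rowwise_minmax(d1$matrix))
})

test_that("filter-impute-normalize preserves samples and labels", {
  study <- small_study()
  ds <- study$datasets[[1]]
  out <- normalize_dataset(impute_missing(filter_features(ds)))
  expect_identical(colnames(out$matrix), colnames(ds$matrix))
  expect_identical(out$labels, ds$labels)
})

test_that("batch correction removes most of a planted batch separation", {
  set.seed(31)
  n_g <- 60; n_s <- 14
  base <- matrix(rnorm(n_g * n_s, 5), n_g, n_s,
                 dimnames = list(sprintf("G%02d", 1:n_g),
                                 sprintf("A_S%02d", 1:n_s)))
  shifted <- base + rnorm(n_g, 2, 0.3)   # per-gene additive batch shift
  colnames(shifted) <- sprintf("B_S%02d", 1:n_s)
  m <- cbind(base, shifted)
  samples <- colnames(m)
  labels <- stats::setNames(rep(c("case", "control"), n_s), samples)
  batch <- stats::setNames(rep(c("A", "B"), each = n_s), samples)
  prof <- disease_profile(m, labels, batch, "PAH")
  corrected <- batch_correct(prof)
  # empirical-Bayes shrinkage leaves residuals on the order of the batch-mean
  # sampling noise, so the guarantee is a strong reduction, not exact equality
  sep_before <- mean(abs(rowMeans(base) - rowMeans(shifted)))
  sep_after <- mean(abs(
    rowMeans(corrected$matrix[, batch == "A"]) -
    rowMeans(corrected$matrix[, batch == "B"])))
  expect_lt(sep_after, 0.15 * sep_before)
  sil_before <- batch_silhouette(m, batch)
  sil_after <- batch_silhouette(corrected$matrix, batch)
  expect_lt(sil_after, sil_before)
  # single batch: identity
  solo <- disease_profile(base, labels[1:n_s],
                          stats::setNames(rep("A", n_s), colnames(base)), "PAH")
  expect_identical(batch_correct(solo)$matrix, base)
})

test_that("batch correction is invariant to consistent column permutation", {
  set.seed(7)
  m <- matrix(rnorm(40 * 12, 5), 40, 12,
              dimnames = list(sprintf("G%02d", 1:40), sprintf("S%02d", 1:12)))
  m[, 7:12] <- m[, 7:12] + 1.5
  labels <- stats::setNames(rep(c("case", "control"), 6), colnames(m))
  batch <- stats::setNames(rep(c("A", "B"), each = 6), colnames(m))
  prof <- disease_profile(m, labels, batch, "IS")
  perm <- sample(ncol(m))
  prof_p <- disease_profile(m[, perm], labels[perm], batch[perm], "IS")
  a <- batch_correct(prof)$matrix
  b <- batch_correct(prof_p)$matrix
  expect_equal(b[, colnames(a)], a)
})

test_that("singleton batches trigger the location-only fallback", {
  set.seed(13)
  m <- matrix(rnorm(30 * 7, 5), 30, 7,
              dimnames = list(sprintf("G%02d", 1:30), sprintf("S%d", 1:7)))
  labels <- stats::setNames(rep(c("case", "control"), length.out = 7),
                            colnames(m))
  batch <- stats::setNames(c(rep("A", 3), rep("B", 3), "C"), colnames(m))
  prof <- disease_profile(m, labels, batch, "PE")
  expect_warning(out <- batch_correct(prof), "location-only")
  expect_equal(dim(out$matrix), dim(m))
})

test_that("outlier masking matches the linear-interpolation quantile oracle", {
  m <- matrix(1:11, 1, 11,
              dimnames = list("A", sprintf("S%02d", 1:11)))
  labels <- stats::setNames(rep(c("case", "control"), length.out = 11),
                            colnames(m))
  batch <- stats::setNames(rep("D", 11), colnames(m))
  prof <- mask_outliers(disease_profile(m, labels, batch, "IS"))
  # P10 = 2 and P90 = 10 under type-7 quantiles: 1 and 11 are masked
  expect_identical(which(is.na(prof$matrix["A", ])), c(S01 = 1L, S11 = 11L))
  # constant row: nothing masked
  cm <- matrix(5, 1, 11, dimnames = dimnames(m))
  expect_false(anyNA(mask_outliers(
    disease_profile(cm, labels, batch, "IS"))$matrix))
  # identity bounds mask nothing
  expect_false(anyNA(mask_outliers(
    disease_profile(m, labels, batch, "IS"), lo = 0, hi = 1)$matrix))
})

test_that("outlier masking never exceeds the percentile budget", {
  set.seed(17)
  for (trial in 1:10) {
    n <- sample(5:40, 1)
    m <- matrix(rnorm(3 * n), 3, n,
                dimnames = list(c("A", "B", "C"), sprintf("S%02d", 1:n)))
    labels <- stats::setNames(rep(c("case", "control"), length.out = n),
                              colnames(m))
    batch <- stats::setNames(rep("D", n), colnames(m))
    prof <- mask_outliers(disease_profile(m, labels, batch, "IS"),
                          lo = 0.1, hi = 0.9)
    masked_per_gene <- rowSums(is.na(prof$matrix))
    expect_true(all(masked_per_gene <= ceiling(n * 0.1) + ceiling(n * 0.1)))
  }
})

test_that("pan-disease profile keeps only case columns", {
  study <- small_study()
  prof <- build_pan_profile(study$datasets[1:4])
  expect_true(all(prof$labels == "case"))
  expect_equal(prof$disease, "pan")
  expect_gt(length(unique(prof$batch)), 1)
})
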