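test_that("PCA layer weights match closed forms and brute-force eigenvectors", {
  set.seed(21)
  x <- rnorm(60)
  # two perfectly correlated informative layers, two zero-variance layers
  s <- cbind(L1 = x, L2 = 2 * x + 5, L3 = 0, L4 = 1)
  w <- pca_layer_weights(s)
  expect_equal(unname(w), c(0.5, 0.5, 0, 0))
  expect_equal(sum(w), 1)
  # sign-flipping a layer leaves its weight unchanged (absolute loadings)
  s2 <- cbind(L1 = x, L2 = -(2 * x + 5), L3 = rnorm(60))
  expect_equal(pca_layer_weights(s2)[["L2"]],
               pca_layer_weights(cbind(L1 = x, L2 = 2 * x + 5,
                                       L3 = s2[, "L3"]))[["L2"]],
               tolerance = 1e-8)
  # brute-force oracle: leading eigenvector of the correlation matrix
  s3 <- matrix(rnorm(50 * 4), 50, 4,
               dimnames = list(NULL, paste0("L", 1:4)))
  ev <- eigen(stats::cor(s3))$vectors[, 1]
  expect_equal(unname(pca_layer_weights(s3)), abs(ev) / sum(abs(ev)),
               tolerance = 1e-8)
  # all-zero-variance input degenerates to uniform weights with a warning
  expect_warning(wu <- pca_layer_weights(cbind(L1 = rep(1, 5), L2 = rep(2, 5))),
                 "uniform")
  expect_equal(unname(wu), c(0.5, 0.5))
})

test_that("final score is the weighted sum of z-standardized layers", {
  set.seed(22)
  s <- matrix(runif(40 * 6), 40, 6, dimnames = list(NULL, paste0("L", 1:6)))
  w <- rep(1 / 6, 6)
  gf <- final_score(s, w)
  # a gene at every layer mean scores 0
  z <- scale(s)
  expect_equal(unname(gf), unname(drop(z %*% w)))
  # a gene at all layer means scores exactly 0
  s0 <- rbind(c(1, rep(0.5, 5)), c(0, rep(0.5, 5)), c(0.5, rep(0.5, 5)))
  colnames(s0) <- paste0("L", 1:6)
  gf0 <- final_score(s0, w)
  expect_equal(gf0[3], 0)   # at all layer means
  # affine rescaling of a raw layer does not change GF
  s_res <- s; s_res[, 2] <- 10 * s[, 2] + 3
  expect_equal(final_score(s_res, w), gf)
})

test_that("score matrix assembly has one 7-column block per disease", {
  set.seed(23)
  mk <- function(genes) {
    m <- matrix(runif(length(genes) * 6), length(genes), 6,
                dimnames = list(genes, c("Gc", "Gp", "GT", "GP", "GM", "GTS")))
    m
  }
  ls <- list(PAH = mk(c("A", "B")), HAPC = mk(c("B", "C")),
             IS = mk(c("A", "C")), PE = mk(c("A", "B")))
  gf <- lapply(ls, function(m) final_score(m, rep(1 / 6, 6)))
  h <- assemble_hirdp(ls, gf)
  expect_equal(ncol(h), 28)
  expect_equal(rownames(h), c("A", "B", "C"))
  expect_identical(colnames(h)[1:7],
                   paste("PAH", c("Gc", "Gp", "GT", "GP", "GM", "GTS", "GF"),
                         sep = "."))
  # genes absent from a disease carry NA in its block
  expect_true(all(is.na(h["C", 1:7])))
  expect_false(anyNA(h["B", 1:7]))
  # a single disease gives a 7-column matrix
  expect_equal(ncol(assemble_hirdp(ls[1], gf[1])), 7)
  # row content is stable under disease-block permutation
  h2 <- assemble_hirdp(ls[c(3, 1, 2, 4)], gf[c(3, 1, 2, 4)])
  expect_equal(h2[, colnames(h)], h)
})

test_that("gene grouping partitions the universe by presence count", {
  pres <- rbind(G1 = c(FALSE, FALSE, FALSE, FALSE),
                G2 = c(TRUE, FALSE, FALSE, FALSE),
                G3 = c(TRUE, TRUE, FALSE, FALSE),
                G4 = c(TRUE, TRUE, TRUE, FALSE),
                G5 = c(TRUE, TRUE, TRUE, TRUE))
  colnames(pres) <- c("PAH", "HAPC", "IS", "PE")
  g <- group_genes(pres)
  expect_equal(as.character(g),
               c("Unrelated", "Unique", "Shared-2", "Shared-3", "Pan-disease"))
  expect_identical(levels(g), c("Unrelated", "Unique", "Shared-2",
                                "Shared-3", "Pan-disease"))
  expect_equal(sum(table(g)), nrow(pres))
})

test_that("biomarker set algebra matches hand enumeration", {
  deg <- list(HAPC = c("A", "B", "C"), PAH = c("B", "C", "D"),
              IS = "C", PE = character(0))
  sets <- derive_biomarker_sets(deg)
  expect_equal(sets$bio_trans, "B")
  expect_equal(sets$raw_trans, c("B", "C"))
  expect_equal(sets$bio_is, character(0))   # C is shared with HAPC/PAH
  expect_equal(sets$bio_pah, "D")
  expect_equal(sets$bio_hapc, "A")
  expect_equal(sets$bio_pe, character(0))
  # identical sets: every specific set empty
  same <- list(HAPC = c("X", "Y"), PAH = c("X", "Y"),
               IS = c("X", "Y"), PE = c("X", "Y"))
  s2 <- derive_biomarker_sets(same)
  expect_true(all(lengths(s2[c("bio_hapc", "bio_pah", "bio_is", "bio_pe")]) == 0))
  # disjoint sets: bio_X = DEG_X and no trans genes
  disj <- list(HAPC = "A", PAH = "B", IS = "C", PE = "D")
  s3 <- derive_biomarker_sets(disj)
  expect_equal(s3$bio_trans, character(0))
  expect_equal(s3$bio_hapc, "A")
  expect_equal(s3$bio_pe, "D")
})

test_that("trans biomarkers never overlap the excluded diseases' DEGs", {
  set.seed(77)
  for (trial in 1:25) {
    pool <- sprintf("G%03d", 1:60)
    deg <- list(HAPC = sample(pool, 25), PAH = sample(pool, 25),
                IS = sample(pool, 15), PE = sample(pool, 15))
    sets <- derive_biomarker_sets(deg)
    expect_length(intersect(sets$bio_trans, union(deg$IS, deg$PE)), 0)
    expect_true(all(sets$bio_trans %in% intersect(deg$HAPC, deg$PAH)))
    for (d in names(deg)) {
      rest <- unlist(deg[setdiff(names(deg), d)])
      expect_length(intersect(sets[[paste0("bio_", tolower(d))]], rest), 0)
    }
  }
})

test_that("cross-disease score tests behave at null and under shift", {
  set.seed(55)
  null_gf <- matrix(rnorm(800 * 4), 800, 4,
                    dimnames = list(sprintf("G%03d", 1:800),
                                    c("PAH", "HAPC", "IS", "PE")))
  res <- gf_group_tests(null_gf)
  expect_gte(res$omnibus_p, 0.05)
  expect_equal(diag(res$pairwise), rep(1, 4), ignore_attr = TRUE)
  expect_equal(res$pairwise, t(res$pairwise))
  shifted <- null_gf; shifted[, "PE"] <- shifted[, "PE"] + 3
  res2 <- gf_group_tests(shifted)
  expect_lt(res2$omnibus_p, 1e-3)
  expect_lt(res2$pairwise["PE", "IS"], 1e-3)
})

test_that("clustering recovers well-separated blobs and is deterministic", {
  set.seed(66)
  blob1 <- matrix(rnorm(40 * 4, 0), 40, 4)
  blob2 <- matrix(rnorm(40 * 4, 10), 40, 4)
  gf <- rbind(blob1, blob2)
  rownames(gf) <- sprintf("G%03d", 1:80)
  colnames(gf) <- c("PAH", "HAPC", "IS", "PE")
  hier <- cluster_gf(gf, "hierarchical", k = 2)
  expect_equal(length(unique(hier$labels[1:40])), 1)
  expect_equal(length(unique(hier$labels[41:80])), 1)
  expect_false(hier$labels[1] == hier$labels[41])
  km <- cluster_gf(gf, "kmeans", k = 2, seed = 0)
  expect_equal(length(unique(km$labels[1:40])), 1)
  expect_identical(km$labels,
                   cluster_gf(gf, "kmeans", k = 2, seed = 0)$labels)
  # single row degenerates to one cluster; k too large errors
  expect_equal(unname(cluster_gf(gf[1, , drop = FALSE], k = 1)$labels), 1L)
  expect_error(cluster_gf(gf[1:3, ], k = 5), "exceeds")
  # disease linkage order covers all diseases
  expect_setequal(hier$disease_order, colnames(gf))
})

test_that("hypergeometric ORA equals tail enumeration on the toy example", {
  universe <- sprintf("U%02d", 1:20)
  gene_set <- list(S1 = universe[1:5])
  query <- c(universe[1:4], universe[10])
  res <- ora_hypergeometric(query, universe, gene_set)
  expect_equal(res$p, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$overlap, 4)
  # brute-force tail: sum over overlap >= 4 of C(5,k) C(15,5-k) / C(20,5)
  brute <- sum(choose(5, 4:5) * choose(15, 1:0)) / choose(20, 5)
  expect_equal(res$p, brute)
  # disjoint query: p = 1
  res2 <- ora_hypergeometric(universe[6:10], universe,
                             list(S1 = universe[1:5]))
  expect_equal(res2$p, 1)
  # set == universe: overlap = |query|, p = 1
  res3 <- ora_hypergeometric(query, universe, list(S1 = universe))
  expect_equal(res3$overlap, 5)
  expect_equal(res3$p, 1)
  # empty query: empty table
  expect_equal(nrow(ora_hypergeometric(character(0), universe, gene_set)), 0)
})

test_that("high-evidence genes rise to the top GF decile on fixtures", {
  study <- small_study()
  ids <- grep("^PAH_", names(study$datasets), value = TRUE)
  prof <- build_disease_profile(study$datasets[ids])
  deg <- build_deg_table(prof)
  s <- compute_layer_scores(study$bundle, deg)
  gf <- final_score(s)
  he <- intersect(study$truth$high_evidence_genes, names(gf))
  expect_gt(length(he), 5)
  mean_rank_frac <- mean(rank(-gf)[he]) / length(gf)
  expect_lte(mean_rank_frac, 0.10)
})
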