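Package: hirisk
Title: Cross-Omics Risk Assessment for Hypoxia-Ischemia Disease Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-disease expression profiles from heterogeneous
    transcriptomic studies of hypoxia-ischemia (H-I) diseases (feature
    filtering, zero imputation, min-max normalization, gene-intersection
    merging, ComBat batch correction, percentile outlier masking), performs
    Wilcoxon rank-sum differential expression with Benjamini-Hochberg
    correction and fold-change categorization, computes six per-gene
    evidence scores (ClinVar variant load, pLI constraint, transcriptome
    significance, protein-interaction degree, dominant metabolic pathway
    membership, tissue specificity) and integrates them into a PCA-weighted
    final risk score per disease. Downstream tools group genes by
    cross-disease presence, derive shared and disease-specific biomarker
    sets, compare score distributions across diseases, cluster the score
    matrix, and run hypergeometric over-representation tests. A seeded
    synthetic-data generator with planted differential expression, batch
    effects and matched annotations makes the whole pipeline testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sva,
    igraph,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
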