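---
title: "Cross-omics risk scoring of hypoxia–ischemia disease profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-omics risk scoring of hypoxia-ischemia disease profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hirisk)
```

## The problem

Hypoxia–ischemia (H-I) diseases — pulmonary arterial hypertension (PAH),
high-altitude polycythemia (HAPC), ischemic stroke (IS) and
eclampsia/preeclampsia (PE) — share pathophysiology around oxygen supply and
vascular function, but the public expression studies that cover them are
small, heterogeneous and platform-mixed. hirisk turns such a collection of
case/control gene-expression studies into comparable per-disease risk
profiles: it merges the studies per disease, calls differentially expressed
genes, scores each gene on six independent evidence layers, and integrates
the layers into one final risk score per gene and disease. Genes can then be
compared *across* diseases: grouped by how many diseases they appear in,
reduced to shared or disease-specific biomarker candidate sets, and
clustered.

## Preprocessing model

Each study is a gene × sample intensity matrix with case/control labels.
Per disease the chain is:

1. **Feature filter.** Genes that are zero *or* missing in more than 75% of
   a study's samples are removed (zeros and missing values are one state at
   this point: mixed microarray/RNA-seq sources do not distinguish them
   reliably). A gene at exactly the threshold is retained.
2. **Imputation.** Remaining missing values become zeros.
3. **Row min-max.** Every gene is rescaled to [0, 1] within its study:
   `(v − min)/(max − min)`. A constant gene maps to all zeros — it carries
   no signal and dividing by a zero range would fabricate variance.
4. **Merge.** Studies of one disease are merged on the *intersection* of
   their gene symbols (a union would impute entire missing studies with
   zeros), columns concatenated, the source study retained as the batch
   label, and each merged row min-max normalized again.
5. **Batch correction.** Parametric empirical-Bayes location/scale
   adjustment — the ComBat model, called through `sva::ComBat` — removes
   per-study shifts and scale distortions. Corrected values may leave
   [0, 1]; they are deliberately not re-normalized, because a third
   normalization would reintroduce relative distortions between batches.
   A single-batch profile is returned unchanged; a batch with fewer than
   two samples triggers ComBat's location-only fit, with a warning.
   Note that empirical-Bayes shrinkage is not an exact mean-matching
   operation: residual per-batch mean differences on the order of the
   sampling noise of batch means remain by design, which is why the test
   suite asserts a strong *reduction* of batch separation (and of the batch
   silhouette), not equality.
6. **Outlier masking.** Per gene, values strictly outside the 10th–90th
   percentile band (linear-interpolation quantiles, R type 7 — stated so
   results are bit-reproducible) are masked as missing. Masking rather than
   deleting samples keeps labels aligned across genes, since the exclusion
   happens after merging. Masked entries are excluded from every downstream
   statistic.

A pan-disease profile (all diseases, case columns only) can be built with
`build_pan_profile()`; the per-disease profiles drive everything downstream.

## Differential expression

Per gene, a two-sided Wilcoxon rank-sum test compares unmasked case against
control values: exact null distribution when the smaller arm has ≤ 8
observations and no ties, normal approximation with tie and continuity
correction otherwise. Two-sided is assumed throughout. P-values are BH
(Benjamini–Hochberg) adjusted across genes. Fold change is
`(stat(case)+ε)/(stat(control)+ε)` with `stat` the median for single
studies (robust to outliers) and the mean for merged profiles (stable
across aggregated samples); `ε = 1e-8` keeps the ratio finite on min-max
scaled data where group medians are frequently 0. A gene is up-regulated if
FC > 1 and FDR ≤ 0.05, down-regulated if FC < 1 and FDR ≤ 0.05, otherwise
non-significant (this includes FC = 1 and degenerate tests).

## The six evidence layers

All layers map into [0, 1]; min-max pools are taken per disease over that
disease's retained gene universe, because the layers are combined per
disease. Genes missing from an annotation source score 0 on that layer —
absence of evidence contributes no risk.

| Layer | Input | Formula |
|---|---|---|
| `Gc` | ClinVar-style variant count | `minmax(log(count + 1))` |
| `Gp` | pLI constraint | `minmax(log(pLI + 1e-12))` |
| `GT` | DEG p-value | `1 − p` |
| `GP` | PPI network degree | `minmax(log(degree + 1))` |
| `GM` | pathway membership | `n_dominant / N_total` if the gene is in the dominant pathway, else 0 |
| `GTS` | gene × tissue specificity | `(TScount / 32) × minmax(TStotal)` |

Details and conventions:

* `Gc`/`GP` are invariant to the logarithm base (an affine factor absorbed
  by min-max) and weakly monotone in their raw inputs.
* `GM`: the dominant pathway is the one with the highest membership count
  over the universe, ties broken lexicographically by pathway id so runs
  are deterministic; `N_total` counts genes with at least one pathway. The
  score structurally takes at most two distinct values per disease.
* `GTS`: `TStotal` is the row sum of tissue specificity scores, `TScount`
  the number of tissues strictly above 2.5; the normalizing constant 32 is
  the tissue count of the reference panel.
* Degenerate pools (all raw values equal) map to all zeros.

## PCA weighting and the final score

For one disease, the gene × 6 layer matrix is z-standardized per layer;
zero-variance layers are dropped (their loadings are undefined) and receive
weight 0. The weight of layer *i* is `|loading_i| / Σ|loading_j|` from the
first principal component, which captures the maximum shared variance
across layers; weights are non-negative and sum to 1. The final score is
`GF(g) = Σ w_i · S_i(g)` over the z-standardized layer scores `S_i`, making
GF invariant to affine rescaling of any raw layer. If *every* layer is
constant, uniform weights are used and a warning raised.

The per-disease blocks (`Gc, Gp, GT, GP, GM, GTS, GF`) are assembled into
one gene × (disease, layer) matrix — 28 columns for the four-disease
design — with `NA` for genes a disease did not retain.

## Grouping, biomarker sets, comparisons

**Presence.** By default a gene is "present" in a disease when it is a DEG
there (`presence_mode = "deg"`); presence by mere profile retention is the
alternative (`"profile"`). The DEG reading is the default because the
biomarker-set algebra is defined on differential expression, and retention
alone would leave the "Unrelated" group nearly empty.

**Groups.** Presence count 0 → Unrelated, 1 → Unique, 2 → Shared-2, 3 →
Shared-3, all → Pan-disease; the labels partition the universe (the union
of all raw features across studies).

**Biomarker sets.** The trans set keeps genes differentially expressed in
both diseases of a designated pair (default HAPC and PAH) and in neither of
the others: `bio_trans = (DEG_HAPC ∩ DEG_PAH) \\ (DEG_IS ∪ DEG_PE)`. Each
disease-specific set subtracts all other diseases' DEGs. Biomarker *type*
labels (direct / intermediate crucial / potential minor-effect) are
literature-curated input joined from an optional TSV, never inferred.

**Score comparisons.** For genes scored in all diseases, a Kruskal–Wallis
omnibus test compares GF across diseases, followed by pairwise two-sided
Wilcoxon rank-sum tests with BH adjustment.

**Clustering.** Genes present in at least three diseases are clustered on
their GF vectors: hierarchical clustering with Euclidean distance and
Ward's ward.D2 linkage (deterministic; the disease dendrogram order is also
reported), or k-means with k = 4 (the number of diseases) and a fixed seed
of 0 by default. Missing entries are imputed with column means for the
distance computation only.

**Over-representation.** A generic one-sided hypergeometric tail test per
gene set (GMT input) against a user universe, BH-adjusted, flagged at
p ≤ 0.05.

## What the synthetic generator emulates

`simulation_config()` fixes the study conditions; the defaults were chosen
once to mirror a realistic multi-study design of this kind and are not
tuning knobs:

* 4 diseases × 2 datasets, 2000 genes, 25 cases and 25 controls per dataset
  — within the range of the public studies such collections draw on;
* log-normal intensities (`exp` of Gaussian log-expression), so min-max
  normalization downstream is meaningful across platforms;
* planted DEGs: 5% of genes shared across disease pairs plus 5%
  disease-specific, disjoint, with random up/down direction and an additive
  effect of 2 pooled SDs on the log scale — large enough that a sound
  pipeline should recover ≥ 80% at FDR 0.05 with 25 samples per arm;
* per-dataset batch distortion: per-gene additive shifts (SD 0.5) and a
  dataset-level multiplicative factor (log-SD 0.1) on the log scale;
* 5% of entries zeroed as "missing" (the generator records the true mask
  separately, since the pipeline conflates zero and missing by design), and
  3% of genes absent per dataset to emulate heterogeneous feature counts;
* a matched annotation bundle in which a small "high-evidence" subset of
  the planted DEGs is boosted on the variant, constraint, degree and
  tissue layers — these genes should surface in the top GF decile;
* one RNG stream per (seed, disease, dataset) tuple, so adding a dataset
  never perturbs previously generated ones.

What it does **not** emulate: platform-specific probe effects, count noise
of real RNA-seq, correlated gene modules, or cell-type mixtures. Passing
tests on these fixtures therefore demonstrates the pipeline's statistical
correctness and calibration, not performance on any particular real
cohort.

## Numerical choices and degenerate inputs

* Constant vectors min-max to zeros everywhere (scores, normalization).
* Quantiles are linear-interpolation (type 7) so masking is reproducible.
* `NaN` p-values (an arm empty after masking) propagate to non-significant
  categories and a transcriptome score of 0.
* BH adjustment passes `NA` through and adjusts the remaining values among
  themselves.
* Dominant-pathway ties break lexicographically; k-means uses a fixed seed;
  Ward.D2 trees are deterministic.
* Empty gene intersections at merge, empty profiles, and k larger than the
  number of genes raise explicit errors.

## Problem sizes used by the test suite

The packaged checks run on 300-gene studies for pipeline-level properties,
2000 genes for the p-value calibration check (Kolmogorov–Smirnov statistic
against uniform < 0.05 under the null configuration), and toy matrices
with hand-enumerable answers for every closed form. The acceptance script
uses a 1000-gene four-disease study. These sizes make the whole suite run
in well under a minute while keeping the statistical assertions
well-powered.

## Known limitations

* The merge-by-intersection strategy discards genes absent from any single
  study of a disease; with many small studies this can be aggressive.
* ComBat assumes roughly Gaussian per-gene intensities; min-max-scaled
  data satisfy this only approximately.
* GM's dominant-pathway construction makes it a two-valued score; it
  contributes little gradient to the PCA weighting by design.
* The pipeline treats annotation layers as disease-independent unless the
  user supplies disease-conditioned files (both are accepted).
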