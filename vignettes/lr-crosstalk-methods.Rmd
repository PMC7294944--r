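---
title: "Methods: ligand-receptor crosstalk inference and its synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-receptor crosstalk inference and its synthetic test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrcrosstalk)
```

`lrcrosstalk` infers ligand-receptor (LR) mediated communication between
tumor cells and T cells in lung adenocarcinoma (LUAD) from single-cell UMI
counts, validates candidate pairs in bulk tumor RNA-seq, screens pair genes
for survival association, and trains a stage-based prognostic classifier.
This vignette is the package's account of the statistics at each stage, of
the synthetic study used to test them, and of the numerical conventions
that make runs reproducible.

## Cell quality control

A cell is removed when any of three criteria holds: fewer than 101 or more
than 6,000 detected genes, or a mitochondrial or ribosomal UMI fraction at
or above 10%. Mitochondrial genes are recognized by the `MT-` symbol
prefix, ribosomal genes by `RPL`/`RPS`; both sets are configurable
(`qc_config()`). The 10% rule is read distributively — each fraction is
checked against the threshold on its own — because a cell can be
compromised by either signal independently; a combined-sum reading is
available via `combine_mito_ribo = TRUE` for sensitivity analyses.
Removal counts are logged per criterion so that cohort attrition is
auditable in the run manifest.

## Normalization, variable genes, embedding, clustering

Counts are scaled per cell to 10,000 total and log1p-transformed, the
standard single-cell normalization. Highly variable genes (default 1,500)
are ranked by *standardized variance*: each gene's values are z-scored
using a trend-fitted standard deviation and clipped at `sqrt(n_cells)`,
and the variance of the clipped z-scores is the ranking statistic. The
mean-variance trend is a binned fit — 20 equal-occupancy bins of the gene
means, trend variance the median gene variance per bin — a deliberately
smoother-free construction that is deterministic and easy to audit. Ties
break by gene symbol ascending so rankings are total orders.

PCA runs on the variable genes scaled to unit variance with values clipped
at ±10 (the clip bounds the influence of extreme cells). Components follow
a fixed sign convention — the largest-magnitude loading is made positive —
so embeddings are identical across runs and platforms. Cells are clustered
by k-means on the top 20 components with k = 9, mirroring the cluster
granularity typical of LUAD cohorts where only tumor, alveolar-epithelial
and T-cell clusters feed the downstream analysis. Initialization is greedy
k-means++ (each new center is the best of `2 + floor(log k)` candidates
drawn proportional to squared distance from existing centers) with 50
restarts at a fixed seed, keeping the lowest-inertia solution. Plain
k-means++ with few restarts was observed to settle into local optima that
split large clusters while merging small distant ones; greedy seeding with
more restarts reliably reaches the lower-inertia solution at negligible
cost (the embedding is only cells × 20). Labels are relabeled 1..k by
decreasing size.

Clusters become compartments by marker scoring: a compartment's score in a
cluster is the mean, over its marker panel, of the cluster-mean z-scored
expression. Panels default to EPCAM/MDK/SOX4 (tumor), FOLR1/SFTPD/AGR3
(normal alveolar epithelium) and CD3D/TRAC/TRBC2 (T cells). A cluster is
assigned the argmax compartment only when (i) that score is positive —
the cluster actually over-expresses the markers — and (ii) it beats the
runner-up by the assignment margin (default 0.25 on the z scale);
otherwise it is `unassigned`. Tumor and normal-epithelial calls must also
agree with the cluster's majority tissue, reflecting that cancer clusters
derive from tumor samples and alveolar clusters from normal tissue.
T cells are then split into tumor-derived and normal-derived by each
cell's own tissue label. UMAP is deliberately absent from the inference
path: it would only serve visualization, and `plot_cell_pca()` renders the
PCA layout instead.

## Hurdle differential expression

Single-cell expression is zero-inflated relative to its positive support,
so each gene is tested with a two-part hurdle:

* **Detection component** — a likelihood-ratio (G) test of equal Bernoulli
  detection probability on the 2×2 detected-by-group table, 1 df.
* **Continuous component** — the squared Welch t statistic on
  log-normalized values among detected cells, 1 df, skipped (statistic 0)
  when either group has fewer than two detected cells.

The combined statistic is the sum, referred to chi-squared with df equal to
the number of contributing components. Genes detected in neither group are
dropped. The log2 fold change uses group means on the de-logged 10k scale
with pseudocount 1. Direction calls use raw *P* < 0.05 by default — the
convention for this screen, where the co-expression stage downstream
carries the multiplicity control — with a BH option exposed, and the run
manifest logs both raw-P and BH DEG counts. Covariate-adjusted hurdle
variants (e.g. detection rate as a covariate) are out of scope; label
exchange symmetry (lfc flips, *P* invariant) and a type-I error within
[0.035, 0.065] on negative-binomial nulls at 200 cells/group are enforced
by the test suite.

## LR pair inference and co-expression validation

From a two-column (ligand, receptor) catalog, matched by exact uppercased
gene symbol:

* **Intracellular pairs**: ligand and receptor both `up` (or both `down`)
  in one compartment's tumor-vs-normal DE table.
* **Crosstalk pairs**: ligand `up` in the source compartment's contrast and
  receptor `up` in the target's, tagged tumor→T or T→tumor. "Highly
  expressed" is operationalized as the DE up label — the natural reading
  when the only available evidence is the two tumor-vs-normal contrasts.

Every candidate must then replicate in bulk tumors: tie-corrected Spearman
correlation (Pearson on mid-ranks; *P* from the t approximation
`t = ρ√((n−2)/(1−ρ²))`, df = n−2) with ρ > 0.4 and BH-adjusted *P* < 0.05.
Adjustment happens within each pair family per run, matching how pair
counts are reported per analysis; Holm is available
(`coexpr_config(adjust_method = "holm")`) since base R's `p.adjust`
defaults to it, but BH is the genomics convention and the default here.
Validation applies uniformly to all pair categories. Spearman's rank basis
makes the stage invariant to any monotone transform of bulk expression,
which the suite verifies explicitly — hence the bulk scale convention
(log2-like continuous values) cannot affect the calls.

## Survival screening

Each gene splits the cohort at its median expression across all samples
(midpoint of central order statistics for even n); ties at the median go to
the low group, so `high` means strictly greater. Constant genes are
unsplittable and reported separately. High vs low survival is compared by
the Kaplan-Meier product-limit estimator and the log-rank test (standard
observed-minus-expected with hypergeometric variance; both delegated to
the `survival` package), significant at raw *P* < 0.05 — no correction, as
is conventional for this screen — with BH-adjusted values reported
alongside for the reader.

## Prognostic classifier

Stage IA patients are low risk; IB-IV high risk (stage spellings are
normalized first; unparseable stages are excluded and counted). The
feature matrix is the bulk expression of every gene appearing in any LR
pair call. A 3:1 stratified random split feeds an XGBoost binary
classifier — 300 trees, depth 3, learning rate 0.1, single-threaded with a
fixed seed so importances are reproducible. Hyperparameters are pinned in
the config and recorded in the manifest rather than tuned: the model's
role is to measure whether LR pair expression carries stage signal, not to
maximize it. Precision/recall/F1 are reported for the high-risk positive
class — the clinically salient one — and as macro averages, so either
convention can be checked against the emitted confusion matrix. Gain-based
importances are ranked with ties broken by feature name.
`pca_label_overlap()` summarizes how mixed the two risk groups are in PC1-2
with the mean silhouette width (values near zero mean the groups overlap,
as stage-derived labels typically do), and `predict_risk()` applies the
fitted model to an external cohort without stage labels, splitting it by
predicted risk and comparing survival by log-rank.

## The synthetic study

Restricted access to the motivating cohorts makes a generator with planted
truth the test substrate. `simulate_sc()` draws UMI counts from
`NB(mean = baseline_g × sizefactor_c × fold(compartment, g), size = 2)`
with lognormal cell size factors (no explicit zero inflation — NB dropout
at low means already exercises the hurdle's detection component):

* **Cohort structure**: 4 tumor and 3 normal samples, 600 cells each.
  Tumor samples contain tumor-epithelial and tumor-derived T cells, normal
  samples their counterparts, each 45% of the sample, plus 10% "other"
  cells drawn from five marker-bearing subtypes (myeloid, fibroblast,
  endothelial, B, mast) that the clustering must reject — mirroring real
  cohorts where only a minority of the ~9 clusters feed the analysis.
* **Markers and programs**: each target compartment's three markers carry
  an 8-fold boost. Each lineage additionally carries a broad lognormal
  expression program (σ = 0.4) over the generic genes, because real cell
  lineages differ transcriptome-wide, not only in markers; contrasted
  pairs (tumor vs normal epithelium; tumor- vs normal-derived T) share
  their lineage program so non-planted genes stay null within each DE
  contrast. On top, tumor-epithelial cells carry a malignancy program and
  tumor-derived T cells an activation/exhaustion program (σ = 0.2),
  restricted to genes not used by any catalog pair — this reproduces the
  empirical regime where the two contrasts show thousands of genuine DEGs
  while planted pair genes and decoys keep their designed behavior.
* **Planted truth**: 10 LR pairs per category (intracellular up, down,
  tumor→T, T→tumor) at 3-fold, 200 decoy pairs with no effect, gene blocks
  with `MT-` and `RPL`/`RPS` prefixes, and 5% each of deliberate QC
  failures (collapsed libraries; 10× mitochondrial load).
* **Bulk cohort** (`simulate_bulk_clinical()`): 200 tumor samples on a
  log2-like continuous scale. Planted pairs share a per-sample latent
  factor weighted so the expected Spearman correlation is 0.6 (via the
  bivariate-normal relation ρ_Pearson = 2 sin(πρ_S/6)); decoy genes are
  independent. Five prognostic genes drawn from the planted pair genes
  get alternating-sign log-hazard coefficients of 0.7 per expression
  z-score; survival is exponential with baseline median ~1000 days and
  independent uniform censoring calibrated by root-finding to a 40%
  censoring fraction. The stage label is drawn from a logistic model on
  the same risk score (slope 1.2, intercept calibrated to the ~72%
  IB-IV prevalence of LUAD cohorts), so the classifier has recoverable —
  but deliberately imperfect — signal.

What passing tests on this generator show, and what they do not: the
pipeline recovers planted effects under NB noise with realistic library
size variation, compartment structure and nuisance populations; the
generator does not model doublets, ambient RNA, batch effects, or
patient-level covariates beyond stage, so robustness to those must come
from the real-data QC and validation stages, not from these tests.

## Numerical conventions and degenerate inputs

* Every stochastic stage derives its RNG stream from the run seed;
  identical config + seed reproduces outputs byte for byte, including the
  JSON manifest (no timestamps in outputs).
* MTX files are 1-based on disk, 0-based in memory, genes as rows;
  duplicate gene symbols gain `.1`, `.2` suffixes in file order; symbols
  are uppercased on ingest and all cross-dataset matching is by exact
  uppercased symbol.
* Constant expression: unsplittable in the survival screen, undefined
  (flagged, excluded) in Spearman validation, never selected as highly
  variable.
* |ρ| = 1 maps to *P* = 0; adjusted *P* values are clipped to [0, 1];
  G-test terms use the 0·log 0 = 0 convention.
* Problem sizes used by the test suite — 4,200 cells × 2,000 genes,
  200 bulk samples, 500 null survival replicates, 20 permutation refits —
  were chosen so the planted effects sit well inside the power of each
  test while a full suite run stays in the low minutes on a laptop.

## Known limitations

Clustering is k-means on PCA rather than graph-based community detection;
it is adequate here because annotation is marker-driven and only needs
compartment separation. The hurdle test omits MAST's covariate adjustment.
The survival screen is univariate (no Cox adjustment). The classifier does
not search hyperparameters or calibrate probabilities. Catalog handling is
a two-column symbol table; identifier mapping beyond symbol matching is
out of scope.
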