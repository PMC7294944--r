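# lrcrosstalk

Ligand–receptor (LR) crosstalk inference for the lung adenocarcinoma (LUAD)
tumor microenvironment, from single-cell UMI counts and bulk RNA-seq.

Tumor cells and infiltrating T cells communicate through ligand–receptor
signaling. `lrcrosstalk` implements a complete, testable pipeline for
finding that communication in transcriptomic data:

1. **Cell QC and annotation** — cells are removed when they detect fewer
   than 101 or more than 6,000 genes, or when ≥ 10% of UMIs map to
   mitochondrial (`MT-`) or ribosomal (`RPL`/`RPS`) genes. Surviving cells
   are library-normalized (10k scaling, log1p), embedded by PCA on the top
   1,500 highly variable genes, clustered by k-means (greedy k-means++
   seeding, k = 9), and clusters are assigned to compartments by marker
   score: tumor cells (EPCAM, MDK, SOX4), normal alveolar epithelium
   (FOLR1, SFTPD, AGR3) and T cells (CD3D, TRAC, TRBC2), with T cells split
   into tumor- and normal-derived by tissue of origin.
2. **Differential expression** — a two-part hurdle test per gene between
   compartments: a likelihood-ratio G-test on detection rates (1 df) plus a
   Welch-style test on log-normalized expression among detected cells
   (1 df), combined as a chi-squared statistic. Genes are called up/down at
   raw *P* < 0.05.
3. **LR pair inference** — from a FANTOM5-style two-column catalog:
   *intracellular* pairs whose ligand and receptor move concordantly
   (both up or both down) within a compartment's tumor-vs-normal contrast,
   and *crosstalk* pairs with the ligand up in one compartment and the
   receptor up in the other (tumor→T and T→tumor directions).
4. **Co-expression validation** — each candidate pair must replicate in a
   bulk tumor cohort: tie-corrected Spearman ρ > 0.4 with
   Benjamini–Hochberg adjusted *P* < 0.05, adjusted within each pair
   family.
5. **Survival screening** — each validated pair gene splits the bulk cohort
   at its median expression (ties go low); high vs low survival is compared
   with Kaplan–Meier curves and the log-rank test at *P* < 0.05.
6. **Prognostic classifier** — AJCC stage IA patients are labeled low risk,
   IB–IV high risk; an XGBoost classifier on the LR pair genes' expression
   (3:1 stratified train/test split, 300 trees, depth 3, learning rate 0.1)
   reports precision/recall/F1 and gain-based feature importances.

Because the data motivating this design are access-restricted, the package
ships a first-class synthetic-data module (`simulate_sc()`,
`simulate_bulk_clinical()`, `simulate_dataset()`) that generates a seeded
multi-sample tumor/normal single-cell cohort with marker-separable
compartments, planted concordant and directional LR pairs, a bulk cohort
with planted pair co-expression, and a clinical table with stage and
right-censored survival — all recorded in a truth manifest so every stage
of the pipeline can be scored against known ground truth.

## Worked example

```r
library(lrcrosstalk)

cfg <- sim_config(seed = 1)                      # the default synthetic study
ds  <- simulate_dataset(cfg, "lrx-demo")         # writes 10x triplet, catalog,
                                                 # bulk, clinical, truth.json
res <- run_all(run_config(
  sc_dir = "lrx-demo/sc",
  catalog_path = "lrx-demo/lr_catalog.tsv",
  bulk_expr_path = "lrx-demo/bulk_expr.tsv",
  bulk_clinical_path = "lrx-demo/clinical.tsv",
  outdir = "lrx-demo-results", seed = 1))

print(ds$cells)
#> <cell_matrix> 2000 genes x 4200 cells
#>   samples: 7 (2400 tumor / 1800 normal cells)

print(res$survival)
#> <survival_screen> 80 genes tested, 8 significant at P < 0.05

print(res$model)
#> <risk_model_report> high-risk precision 0.727 / recall 0.914 / F1 0.810 (macro F1 0.548)
#>   top features: GENE1476, GENE1531, GENE0210, GENE0357, GENE0633

head(tidy(res$model), 3)
#> # A tibble: 3 × 3
#>   feature    gain  rank
#>   <chr>     <dbl> <int>
#> 1 GENE1476 0.149      1
#> 2 GENE1531 0.0998     2
#> 3 GENE0210 0.0582     3
```

All three top-importance genes are planted prognostic genes
(`ds$truth$prognostic`), and the eight survival-significant genes include
all five planted ones. Every stage writes a TSV under `outdir` plus a JSON
run manifest with the counts at each filtering step (cells removed per QC
criterion, DEG counts per contrast, candidate and validated pair counts per
category, survival hits, model metrics); re-running with the same seed
reproduces the manifest byte for byte.

Result objects are tidyverse-friendly: `tidy()`/`glance()` methods for the
survival screen and the risk model, `autoplot()` for DE tables (volcano)
and model importances, plus `plot_km_gene()` and `plot_cell_pca()`.

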