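#' Simulate a multi-sample tumor/normal single-cell cohort with planted truth
#'
#' Draws UMI counts per gene and cell from a negative binomial,
#' `NB(mean = baseline_g * sizefactor_c * fold(compartment, g), size =
#' nb_dispersion)`, with lognormal per-cell size factors. Each target
#' compartment carries three marker genes at `marker_fold`; planted
#' ligand-receptor (LR) genes carry `de_fold` in their flagged compartment;
#' the gene universe includes `MT-` (mitochondrial) and `RPL`/`RPS`
#' (ribosomal) blocks; a controlled proportion of cells is injected as QC
#' failures (high mitochondrial fraction or very low gene detection).
#' Non-target "other" cells are generated as five marker-bearing subtypes
#' (emulating myeloid, fibroblast, endothelial, B and mast populations) so
#' that clustering has to reject them, as in real tumor microenvironment
#' data. Each lineage additionally carries a broad lognormal expression
#' program over the generic genes, so lineages differ transcriptome-wide
#' as real cell types do, while contrasted pairs (tumor vs normal
#' epithelial, tumor- vs normal-derived T) share a program and stay null
#' on non-planted genes.
#'
#' @param config a [sim_config()].
#' @return A list with elements `cells` (a [cell_matrix()]) and `truth`
#'   (a `truth_manifest`: planted pair table with categories, per-gene
#'   planted effects, prognostic genes with signs, per-cell true compartment
#'   and QC-fail flag, and the LR catalog containing every planted and decoy
#'   pair).
#' @export
simulate_sc <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed(child_seed(config$seed, 1L), simulate_sc_impl(config))
}

simulate_sc_impl <- function(cfg) {
  panel <- sim_marker_panel()
  other_markers <- list(other_myeloid = c("CD68", "LYZ", "AIF1"),
                        other_fibroblast = c("DCN", "LUM", "PDGFRB"),
                        other_endothelial = c("PECAM1", "VWF", "CLDN5"),
                        other_B = c("CD79A", "MS4A1", "CD19"),
                        other_mast = c("TPSAB1", "CPA3", "MS4A2"))
  mt_genes <- sprintf("MT-ND%d", 1:10)
  rp_genes <- c(sprintf("RPL%d", 1:10), sprintf("RPS%d", 1:10))
  special <- c(unlist(panel), unlist(other_markers), mt_genes, rp_genes)
  n_generic <- cfg$n_genes - length(special)
  if (n_generic < 100L) stop_input("n_genes too small for the planted design")
  generic <- sprintf("GENE%04d", seq_len(n_generic))
  genes <- c(unlist(panel), unlist(other_markers), mt_genes, rp_genes, generic)
  names(genes) <- NULL

  # baseline per-gene NB means; marker and housekeeping blocks get fixed,
  # well-detected baselines so fractions and folds behave predictably
  baseline <- stats::setNames(rlnorm(cfg$n_genes, meanlog = log(0.5), sdlog = 1.0),
                              genes)
  baseline[unlist(panel)] <- 2.0
  baseline[unlist(other_markers)] <- 2.0
  baseline[mt_genes] <- 5.0
  baseline[rp_genes] <- 6.0

  # planted LR pairs: genes drawn from the generic pool, one pair per gene
  n_planted <- cfg$n_true_pairs_intracellular_up +
    cfg$n_true_pairs_intracellular_down +
    cfg$n_true_crosstalk_tumor_to_T + cfg$n_true_crosstalk_T_to_tumor
  need <- 2L * (n_planted + cfg$n_decoy_pairs)
  if (need > n_generic) stop_input("gene universe too small for requested pairs")
  pool <- sample(generic, need)
  take <- function(k) {
    out <- pool[seq_len(2L * k)]
    pool <<- pool[-seq_len(2L * k)]
    tibble(ligand = out[seq_len(k)], receptor = out[k + seq_len(k)])
  }
  pairs <- bind_rows(
    mutate(take(cfg$n_true_pairs_intracellular_up), category = "intra_up"),
    mutate(take(cfg$n_true_pairs_intracellular_down), category = "intra_down"),
    mutate(take(cfg$n_true_crosstalk_tumor_to_T), category = "tumor_to_T"),
    mutate(take(cfg$n_true_crosstalk_T_to_tumor), category = "T_to_tumor"),
    mutate(take(cfg$n_decoy_pairs), category = "decoy")
  )

  # per-gene fold effects by compartment; intra pairs are planted in the
  # tumor-vs-normal-epithelial contrast, crosstalk ligands/receptors in
  # their source/target compartment's tumor-vs-normal contrast
  effects <- bind_rows(
    pairs |> filter(.data$category == "intra_up") |>
      tidyr::pivot_longer(c("ligand", "receptor"), values_to = "gene") |>
      mutate(compartment = "tumor_epithelial", direction = "up"),
    pairs |> filter(.data$category == "intra_down") |>
      tidyr::pivot_longer(c("ligand", "receptor"), values_to = "gene") |>
      mutate(compartment = "normal_epithelial", direction = "down"),
    pairs |> filter(.data$category == "tumor_to_T") |>
      tidyr::pivot_longer("ligand", values_to = "gene") |>
      mutate(compartment = "tumor_epithelial", direction = "up"),
    pairs |> filter(.data$category == "tumor_to_T") |>
      tidyr::pivot_longer("receptor", values_to = "gene") |>
      mutate(compartment = "T_tumor", direction = "up"),
    pairs |> filter(.data$category == "T_to_tumor") |>
      tidyr::pivot_longer("ligand", values_to = "gene") |>
      mutate(compartment = "T_tumor", direction = "up"),
    pairs |> filter(.data$category == "T_to_tumor") |>
      tidyr::pivot_longer("receptor", values_to = "gene") |>
      mutate(compartment = "tumor_epithelial", direction = "up")
  ) |> select("gene", "compartment", "direction", "category")

  # fold multiplier vectors per generated subtype
  subtype_comp <- c(tumor_epithelial = "tumor_epithelial",
                    normal_epithelial = "normal_epithelial",
                    T_tumor = "T_tumor", T_normal = "T_normal",
                    stats::setNames(rep("other", length(other_markers)),
                                    names(other_markers)))

  # broad lineage expression programs over the generic genes: real cell
  # lineages differ transcriptome-wide, not only in markers. Contrasted
  # pairs (tumor vs normal epithelial; tumor-derived vs normal-derived T)
  # share a program, so non-planted genes stay null within each DE contrast.
  lineage_of <- c(tumor_epithelial = "epithelial",
                  normal_epithelial = "epithelial",
                  T_tumor = "T", T_normal = "T",
                  stats::setNames(names(other_markers), names(other_markers)))
  lineages <- unique(unname(lineage_of))
  program <- sapply(lineages, function(l) {
    f <- rep(1, cfg$n_genes)
    names(f) <- genes
    f[generic] <- exp(rnorm(length(generic), 0, 0.4))
    f
  })

  # contrast-side programs: tumor epithelial cells carry a malignancy
  # program and tumor-derived T cells an activation/exhaustion program
  # (weaker, sigma 0.2), confined to generic genes not used by any
  # catalog pair so planted folds and decoy nulls are undisturbed.
  pair_genes_all <- unique(c(pairs$ligand, pairs$receptor))
  prog_support <- setdiff(generic, pair_genes_all)
  contrast_prog <- sapply(c("tumor_epithelial", "T_tumor"), function(st) {
    f <- rep(1, cfg$n_genes)
    names(f) <- genes
    f[prog_support] <- exp(rnorm(length(prog_support), 0, 0.2))
    f
  })
  fold_for <- function(subtype) {
    f <- rep(1, cfg$n_genes)
    names(f) <- genes
    comp <- subtype_comp[[subtype]]
    if (comp == "tumor_epithelial") f[panel$tumor] <- cfg$marker_fold
    if (comp == "normal_epithelial") f[panel$epithelial] <- cfg$marker_fold
    if (comp %in% c("T_tumor", "T_normal")) f[panel$T] <- cfg$marker_fold
    if (startsWith(subtype, "other_")) f[other_markers[[subtype]]] <- cfg$marker_fold
    # planted DE: effect genes are elevated in their flagged compartment.
    # "down" effects live in normal_epithelial so the tumor contrast sees
    # a decrease; T-contrast effects live in T_tumor.
    eff <- effects[effects$compartment == comp, ]
    if (nrow(eff)) f[eff$gene] <- f[eff$gene] * cfg$de_fold
    f <- f * program[, lineage_of[[subtype]]]
    if (subtype %in% colnames(contrast_prog)) {
      f <- f * contrast_prog[, subtype]
    }
    f
  }

  # sample sheet: matched patients, tumor samples first
  samples <- tibble(
    sample = c(sprintf("T%d", seq_len(cfg$n_samples_tumor)),
               sprintf("N%d", seq_len(cfg$n_samples_normal))),
    patient = c(sprintf("P%d", seq_len(cfg$n_samples_tumor)),
                sprintf("P%d", seq_len(cfg$n_samples_normal))),
    tissue = rep(c("tumor", "normal"),
                 c(cfg$n_samples_tumor, cfg$n_samples_normal))
  )

  cell_rows <- list()
  count_blocks <- list()
  for (i in seq_len(nrow(samples))) {
    smp <- samples[i, ]
    n_c <- cfg$cells_per_sample
    if (smp$tissue == "tumor") {
      subtypes <- c("tumor_epithelial", "T_tumor")
    } else {
      subtypes <- c("normal_epithelial", "T_normal")
    }
    n_other <- length(other_markers)
    probs <- c(rep((1 - cfg$other_frac) / 2, 2),
               rep(cfg$other_frac / n_other, n_other))
    subtype <- sample(c(subtypes, names(other_markers)), n_c,
                      replace = TRUE, prob = probs)
    size_factor <- rlnorm(n_c, cfg$libsize_mu, cfg$libsize_sigma)
    qc_fail <- sample(c("none", "lowgene", "mito"), n_c, replace = TRUE,
                      prob = c(1 - cfg$lowgene_outlier_rate - cfg$mito_frac_outlier_rate,
                               cfg$lowgene_outlier_rate, cfg$mito_frac_outlier_rate))
    mu <- matrix(0, nrow = cfg$n_genes, ncol = n_c,
                 dimnames = list(genes, NULL))
    for (st in unique(subtype)) {
      idx <- which(subtype == st)
      mu[, idx] <- fold_for(st) * baseline
    }
    mu <- sweep(mu, 2, size_factor, `*`)
    # QC-failure injection: lowgene cells get a collapsed library;
    # mito cells get a 10x mitochondrial load
    low <- which(qc_fail == "lowgene")
    if (length(low)) mu[, low] <- mu[, low] * 0.01
    mito <- which(qc_fail == "mito")
    if (length(mito)) mu[mt_genes, mito] <- mu[mt_genes, mito] * 10
    cnt <- matrix(rnbinom(length(mu), size = cfg$nb_dispersion, mu = mu),
                  nrow = cfg$n_genes,
                  dimnames = list(genes,
                                  sprintf("%s_C%04d", smp$sample, seq_len(n_c))))
    count_blocks[[i]] <- Matrix::Matrix(cnt, sparse = TRUE)
    cell_rows[[i]] <- tibble(
      cell_id = colnames(cnt),
      sample = smp$sample, patient = smp$patient, tissue = smp$tissue,
      true_compartment = unname(subtype_comp[subtype]),
      true_subtype = subtype, qc_fail = qc_fail
    )
  }
  counts <- do.call(cbind, count_blocks)
  cell_truth <- bind_rows(cell_rows)

  cells <- cell_matrix(counts,
                       cell_truth |> select("cell_id", "sample", "patient", "tissue"))

  prognostic <- tibble(gene = character(), sign = numeric())
  if (cfg$n_prognostic_genes > 0L) {
    planted_genes <- pairs |> filter(.data$category != "decoy")
    pg <- sample(unique(c(planted_genes$ligand, planted_genes$receptor)),
                 cfg$n_prognostic_genes)
    prognostic <- tibble(gene = pg,
                         sign = rep_len(c(1, -1), cfg$n_prognostic_genes))
  }

  truth <- structure(list(
    pairs = pairs,
    gene_effects = effects,
    prognostic = prognostic,
    cell_truth = cell_truth,
    catalog = lr_catalog(pairs |> select("ligand", "receptor")),
    genes = genes,
    marker_panel = panel,
    config = cfg
  ), class = "truth_manifest")

  list(cells = cells, truth = truth)
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat("<truth_manifest>\n")
  print(count(x$pairs, .data$category))
  cat(sprintf("  prognostic genes: %s\n",
              paste(x$prognostic$gene, collapse = ", ")))
  invisible(x)
}
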