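#' Simulation configuration
#'
#' Parameters of the synthetic study: a multi-sample tumor/normal single-cell
#' cohort with marker-separable compartments and planted ligand-receptor (LR)
#' ground truth, a bulk cohort with planted LR co-expression, and a clinical
#' table with AJCC stage and right-censored survival. Defaults define the
#' study conditions used throughout the package's tests.
#'
#' @param seed integer; fixes every random draw in the module.
#' @param n_genes total number of genes in the universe (includes marker,
#'   mitochondrial `MT-` and ribosomal `RPL`/`RPS` blocks).
#' @param n_samples_tumor,n_samples_normal numbers of tumor / normal
#'   single-cell samples (one patient each plus shared patients for tumor).
#' @param cells_per_sample cells drawn per sample.
#' @param marker_fold multiplicative expression effect of a compartment's
#'   marker genes inside that compartment.
#' @param de_fold fold change of planted differentially expressed (DE) genes
#'   in their flagged compartment.
#' @param nb_dispersion negative-binomial size parameter shared by all genes.
#' @param libsize_mu,libsize_sigma meanlog/sdlog of the lognormal per-cell
#'   size factors.
#' @param mito_frac_outlier_rate,lowgene_outlier_rate proportions of cells
#'   deliberately failing QC (high mitochondrial fraction; too few genes).
#' @param n_true_pairs_intracellular_up,n_true_pairs_intracellular_down
#'   planted concordant LR pairs in the tumor-vs-normal-epithelial contrast.
#' @param n_true_crosstalk_tumor_to_T,n_true_crosstalk_T_to_tumor planted
#'   directional crosstalk pairs (ligand up in source, receptor up in target).
#' @param n_decoy_pairs catalog pairs with no planted effect.
#' @param bulk_n_samples bulk (tumor) cohort size.
#' @param bulk_rho_target expected Spearman correlation of planted pairs in
#'   bulk.
#' @param n_prognostic_genes LR pair genes given a survival effect.
#' @param prognostic_beta log-hazard per unit expression z-score.
#' @param censor_rate_target expected fraction of censored subjects.
#' @param other_frac fraction of cells per sample drawn from the non-target
#'   ("other") compartments.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_samples_tumor = 4L,
                       n_samples_normal = 3L,
                       cells_per_sample = 600L,
                       marker_fold = 8.0,
                       de_fold = 3.0,
                       nb_dispersion = 2.0,
                       libsize_mu = 0,
                       libsize_sigma = 0.3,
                       mito_frac_outlier_rate = 0.05,
                       lowgene_outlier_rate = 0.05,
                       n_true_pairs_intracellular_up = 10L,
                       n_true_pairs_intracellular_down = 10L,
                       n_true_crosstalk_tumor_to_T = 10L,
                       n_true_crosstalk_T_to_tumor = 10L,
                       n_decoy_pairs = 200L,
                       bulk_n_samples = 200L,
                       bulk_rho_target = 0.6,
                       n_prognostic_genes = 5L,
                       prognostic_beta = 0.7,
                       censor_rate_target = 0.4,
                       other_frac = 0.10) {
  cfg <- list(
    seed = assert_count(seed, "seed", min = 0L),
    n_genes = assert_count(n_genes, "n_genes", min = 100L),
    n_samples_tumor = assert_count(n_samples_tumor, "n_samples_tumor"),
    n_samples_normal = assert_count(n_samples_normal, "n_samples_normal"),
    cells_per_sample = assert_count(cells_per_sample, "cells_per_sample"),
    marker_fold = marker_fold,
    de_fold = de_fold,
    nb_dispersion = nb_dispersion,
    libsize_mu = libsize_mu,
    libsize_sigma = libsize_sigma,
    mito_frac_outlier_rate = assert_fraction(mito_frac_outlier_rate,
                                             "mito_frac_outlier_rate"),
    lowgene_outlier_rate = assert_fraction(lowgene_outlier_rate,
                                           "lowgene_outlier_rate"),
    n_true_pairs_intracellular_up =
      assert_count(n_true_pairs_intracellular_up,
                   "n_true_pairs_intracellular_up", min = 0L),
    n_true_pairs_intracellular_down =
      assert_count(n_true_pairs_intracellular_down,
                   "n_true_pairs_intracellular_down", min = 0L),
    n_true_crosstalk_tumor_to_T =
      assert_count(n_true_crosstalk_tumor_to_T,
                   "n_true_crosstalk_tumor_to_T", min = 0L),
    n_true_crosstalk_T_to_tumor =
      assert_count(n_true_crosstalk_T_to_tumor,
                   "n_true_crosstalk_T_to_tumor", min = 0L),
    n_decoy_pairs = assert_count(n_decoy_pairs, "n_decoy_pairs", min = 0L),
    bulk_n_samples = assert_count(bulk_n_samples, "bulk_n_samples", min = 4L),
    bulk_rho_target = bulk_rho_target,
    n_prognostic_genes = assert_count(n_prognostic_genes,
                                      "n_prognostic_genes", min = 0L),
    prognostic_beta = prognostic_beta,
    censor_rate_target = assert_fraction(censor_rate_target,
                                         "censor_rate_target"),
    other_frac = assert_fraction(other_frac, "other_frac", lo = 0, hi = 0.5)
  )
  if (cfg$marker_fold <= 1 || cfg$de_fold <= 1) {
    stop_input("marker_fold and de_fold must exceed 1")
  }
  if (cfg$nb_dispersion <= 0) stop_input("nb_dispersion must be positive")
  if (abs(cfg$bulk_rho_target) >= 1) {
    stop_input("bulk_rho_target must lie in (-1, 1)")
  }
  class(cfg) <- "sim_config"
  cfg
}

# compartment labels used by the simulator and annotation stages
sim_compartments <- function() {
  c("tumor_epithelial", "normal_epithelial", "T_tumor", "T_normal", "other")
}

# default marker panel: three markers per target compartment, mirroring
# the tumor / alveolar-epithelial / T-cell markers used in LUAD studies
sim_marker_panel <- function() {
  list(tumor = c("EPCAM", "MDK", "SOX4"),
       epithelial = c("FOLR1", "SFTPD", "AGR3"),
       T = c("CD3D", "TRAC", "TRBC2"))
}
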