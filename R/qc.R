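#' QC configuration
#'
#' Cell-level quality-control thresholds: cells are removed when the number
#' of detected genes falls below `min_genes` or above `max_genes`, or when
#' the fraction of UMIs mapping to mitochondrial or ribosomal genes reaches
#' `mito_ribo_max_fraction`. By default the fraction rule is applied
#' distributively (mitochondrial OR ribosomal fraction each checked against
#' the threshold); `combine_mito_ribo = TRUE` checks their sum instead.
#'
#' @param min_genes,max_genes detected-gene bounds (inclusive).
#' @param mito_ribo_max_fraction fraction at or above which a cell fails.
#' @param mito_prefixes,ribo_prefixes gene-symbol prefixes identifying
#'   mitochondrial and ribosomal genes.
#' @param combine_mito_ribo check mito+ribo combined instead of separately.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_genes = 101L, max_genes = 6000L,
                      mito_ribo_max_fraction = 0.10,
                      mito_prefixes = "MT-",
                      ribo_prefixes = c("RPL", "RPS"),
                      combine_mito_ribo = FALSE) {
  min_genes <- assert_count(min_genes, "min_genes")
  max_genes <- assert_count(max_genes, "max_genes")
  if (min_genes >= max_genes) stop_input("min_genes must be below max_genes")
  assert_fraction(mito_ribo_max_fraction, "mito_ribo_max_fraction", lo = 1e-9)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 mito_ribo_max_fraction = mito_ribo_max_fraction,
                 mito_prefixes = mito_prefixes, ribo_prefixes = ribo_prefixes,
                 combine_mito_ribo = combine_mito_ribo),
            class = "qc_config")
}

prefix_match <- function(symbols, prefixes) {
  hit <- rep(FALSE, length(symbols))
  for (p in prefixes) hit <- hit | startsWith(symbols, p)
  hit
}

#' Compute per-cell QC statistics
#'
#' @param cells a [cell_matrix()].
#' @param cfg a [qc_config()].
#' @return A tibble: cell_id, n_genes_detected, total_umis, mito_fraction,
#'   ribo_fraction.
#' @export
qc_stats <- function(cells, cfg = qc_config()) {
  m <- cells$counts
  total <- Matrix::colSums(m)
  mito <- prefix_match(rownames(m), cfg$mito_prefixes)
  ribo <- prefix_match(rownames(m), cfg$ribo_prefixes)
  tibble(
    cell_id = colnames(m),
    n_genes_detected = Matrix::colSums(m > 0),
    total_umis = total,
    mito_fraction = ifelse(total > 0, Matrix::colSums(m[mito, , drop = FALSE]) / total, 0),
    ribo_fraction = ifelse(total > 0, Matrix::colSums(m[ribo, , drop = FALSE]) / total, 0)
  )
}

#' Filter cells by quality criteria
#'
#' Retains exactly the cells with `min_genes <= n_genes_detected <=
#' max_genes` and mitochondrial and ribosomal UMI fractions below the
#' threshold. Per-criterion removal counts are attached as the
#' `"qc_removed"` attribute and the per-cell statistics are recorded in the
#' metadata.
#'
#' @param cells a [cell_matrix()].
#' @param cfg a [qc_config()].
#' @return The filtered [cell_matrix()] with QC columns in `cell_meta` and
#'   attribute `qc_removed` (named counts: low_gene, high_gene, mito, ribo,
#'   total_removed, retained).
#' @export
qc_filter <- function(cells, cfg = qc_config()) {
  st <- qc_stats(cells, cfg)
  low <- st$n_genes_detected < cfg$min_genes
  high <- st$n_genes_detected > cfg$max_genes
  if (cfg$combine_mito_ribo) {
    frac_fail <- (st$mito_fraction + st$ribo_fraction) >= cfg$mito_ribo_max_fraction
    mito_fail <- frac_fail
    ribo_fail <- rep(FALSE, nrow(st))
  } else {
    mito_fail <- st$mito_fraction >= cfg$mito_ribo_max_fraction
    ribo_fail <- st$ribo_fraction >= cfg$mito_ribo_max_fraction
  }
  fail <- low | high | mito_fail | ribo_fail
  if (all(fail)) stop_input("all cells removed by QC filtering")
  out <- subset_cells(cells, !fail)
  out$cell_meta <- out$cell_meta |>
    left_join(st, by = "cell_id")
  attr(out, "qc_removed") <- c(
    low_gene = sum(low), high_gene = sum(high),
    mito = sum(mito_fail), ribo = sum(ribo_fail),
    total_removed = sum(fail), retained = sum(!fail)
  )
  out
}

#' Library-size normalization with log transform
#'
#' Scales each cell to 10,000 total counts and applies `log(1 + x)`,
#' the standard single-cell normalization preceding variable-gene selection.
#'
#' @param cells a [cell_matrix()] (QC-passed).
#' @return A sparse genes x cells matrix of normalized values.
#' @export
normalize_log <- function(cells) {
  m <- cells$counts
  total <- Matrix::colSums(m)
  if (any(total == 0)) stop_input("cell with zero total counts; run qc_filter first")
  norm <- m %*% Matrix::Diagonal(x = 1e4 / total)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m)
  methods::as(norm, "CsparseMatrix")
}

#' Select highly variable genes
#'
#' Ranks genes by standardized variance: per-gene values are z-scored with a
#' trend-fitted standard deviation (binned mean-variance trend over 20
#' equal-occupancy bins of the gene means), clipped at `sqrt(n_cells)`, and
#' the variance of the clipped z-scores is the ranking statistic. Ties are
#' broken by gene symbol ascending.
#'
#' @param normalized genes x cells normalized matrix (from [normalize_log()]).
#' @param n_hvg number of genes to return.
#' @param n_bins trend bins.
#' @return Character vector of exactly `n_hvg` gene symbols, ranked.
#' @export
select_hvg <- function(normalized, n_hvg = 1500L, n_bins = 20L) {
  n_hvg <- assert_count(n_hvg, "n_hvg")
  if (nrow(normalized) < n_hvg) {
    stop_input(sprintf("requested %d HVGs but only %d genes available",
                       n_hvg, nrow(normalized)))
  }
  n_cells <- ncol(normalized)
  mu <- Matrix::rowSums(normalized) / n_cells
  # raw variance via sums of squares (sparse-friendly)
  sq <- normalized
  sq@x <- sq@x^2
  v <- (Matrix::rowSums(sq) - n_cells * mu^2) / (n_cells - 1)

  # equal-occupancy bins on the mean; trend sd = sqrt(median bin variance)
  ord <- order(mu)
  bin <- integer(length(mu))
  bin[ord] <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  trend_var <- tapply(v, bin, stats::median)
  sd_trend <- sqrt(pmax(trend_var[as.character(bin)], 1e-12))

  clip <- sqrt(n_cells)
  std_var <- standardized_variance(normalized, mu, sd_trend, clip)
  names(std_var) <- rownames(normalized)
  std_var[v < 1e-12] <- 0   # constant genes can never be selected
  ranked <- names(std_var)[order(-std_var, names(std_var))]
  ranked[seq_len(n_hvg)]
}

# variance of clipped z-scores, computed without densifying:
# for a sparse row, the zero entries contribute the constant z0 = -mu/sd.
standardized_variance <- function(m, mu, sd_trend, clip) {
  n <- ncol(m)
  z0 <- pmax(pmin(-mu / sd_trend, clip), -clip)
  mp <- methods::as(m, "CsparseMatrix")
  # row-wise sums of z and z^2 over NONZERO entries
  ri <- mp@i + 1L
  zx <- (mp@x - mu[ri]) / sd_trend[ri]
  zx <- pmax(pmin(zx, clip), -clip)
  s1 <- rowsum_vec(zx, ri, nrow(m))
  s2 <- rowsum_vec(zx^2, ri, nrow(m))
  nz <- rowsum_vec(rep(1, length(ri)), ri, nrow(m))
  tot1 <- s1 + (n - nz) * z0
  tot2 <- s2 + (n - nz) * z0^2
  (tot2 - tot1^2 / n) / (n - 1)
}

rowsum_vec <- function(x, idx, nrows) {
  out <- numeric(nrows)
  acc <- rowsum(x, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}
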