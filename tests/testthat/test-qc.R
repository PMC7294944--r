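make_qc_toy <- function() {
  # three genes incl. one mitochondrial and one ribosomal, four crafted cells
  genes <- c("MT-ND1", "RPL3", "GENEA")
  cells <- c("keep", "lowgene", "himito", "hiribo")
  m <- matrix(0, 3, 4, dimnames = list(genes, cells))
  m[, "keep"] <- c(5, 3, 92)        # 5% mito, 3% ribo, 3 genes detected
  m[, "lowgene"] <- c(0, 0, 10)
  m[, "himito"] <- c(12, 0, 88)     # 12% mito
  m[, "hiribo"] <- c(0, 15, 85)     # 15% ribo
  toy_cells(m)
}

test_that("qc_filter applies the detected-gene and fraction rules", {
  toy <- make_qc_toy()
  kept <- qc_filter(toy, qc_config(min_genes = 2L, max_genes = 100L))
  expect_equal(colnames(kept$counts), "keep")
  removed <- attr(kept, "qc_removed")
  expect_equal(unname(removed["low_gene"]), 1)
  expect_equal(unname(removed["mito"]), 1)
  expect_equal(unname(removed["ribo"]), 1)
  expect_equal(unname(removed["retained"]), 1)
})

test_that("a cell at 150 genes / 5% mito / 3% ribo is kept; 50 genes or 12% mito removed", {
  set.seed(1)
  n_genes <- 300
  genes <- c("MT-ND1", "RPL3", sprintf("G%03d", 1:(n_genes - 2)))
  mk_cell <- function(n_detected, mito_frac, ribo_frac) {
    v <- numeric(n_genes)
    body <- round(1000 * (1 - mito_frac - ribo_frac))
    idx <- 2 + seq_len(n_detected - 2)
    v[idx] <- as.vector(stats::rmultinom(1, body, rep(1, length(idx))))
    v[idx][v[idx] == 0] <- 1   # ensure the intended detection count
    v[1] <- round(1000 * mito_frac)
    v[2] <- round(1000 * ribo_frac)
    v
  }
  m <- cbind(a = mk_cell(150, 0.05, 0.03),
             b = mk_cell(50, 0.05, 0.03),
             c = mk_cell(200, 0.12, 0.03))
  rownames(m) <- genes
  kept <- qc_filter(toy_cells(m), qc_config())
  expect_equal(colnames(kept$counts), "a")
})

test_that("qc_filter agrees with a brute-force per-cell re-check", {
  st <- default_study()
  cfg <- qc_config()
  set.seed(9)
  pick <- sample(ncol(st$cells$counts), 1000)
  sub <- subset_cells_for_test(st$cells, pick)
  kept <- qc_filter(sub, cfg)
  m <- as.matrix(sub$counts)
  mito <- startsWith(rownames(m), "MT-")
  ribo <- startsWith(rownames(m), "RPL") | startsWith(rownames(m), "RPS")
  brute <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    ng <- sum(v > 0); tot <- sum(v)
    ng >= cfg$min_genes && ng <= cfg$max_genes &&
      sum(v[mito]) / tot < cfg$mito_ribo_max_fraction &&
      sum(v[ribo]) / tot < cfg$mito_ribo_max_fraction
  }, logical(1))
  expect_setequal(colnames(kept$counts), colnames(m)[brute])
})

test_that("normalization scales to 10k and is invariant to cell depth", {
  m <- matrix(c(100, 900, 200, 1800), 2, 2,
              dimnames = list(c("G1", "G2"), c("c1", "c2")))
  norm <- normalize_log(toy_cells(m))
  expect_equal(norm["G1", "c1"], log1p(1000))
  expect_equal(norm["G2", "c1"], log1p(9000))
  # doubling every count leaves the normalized vector unchanged
  expect_equal(norm[, "c1"], norm[, "c2"])
  # all-equal counts give all-equal normalized values
  m2 <- matrix(5, 3, 2, dimnames = list(paste0("G", 1:3), c("a", "b")))
  n2 <- normalize_log(toy_cells(m2))
  expect_true(all(abs(n2 - n2[1, 1]) < 1e-12))
})

test_that("constant genes are never highly variable and ties break alphabetically", {
  set.seed(4)
  m <- rbind(CONST = rep(3, 40),
             VARY1 = rpois(40, 5),
             VARY2 = rpois(40, 5))
  colnames(m) <- paste0("c", 1:40)
  # make the two varying genes exactly tied by duplication
  m["VARY2", ] <- m["VARY1", ]
  norm <- normalize_log(toy_cells(m))
  hv <- select_hvg(norm, 2L, n_bins = 1L)
  expect_false("CONST" %in% hv)
  expect_equal(hv, c("VARY1", "VARY2"))  # tie -> alphabetical
})

test_that("planted DE genes rank among the top highly variable genes", {
  st <- default_study()
  ann <- default_annotated()
  planted <- unique(st$truth$gene_effects$gene)
  expect_gte(mean(planted %in% ann$hvg), 0.8)
})

test_that("PCA embedding is deterministic with the stated sign convention", {
  set.seed(2)
  base <- matrix(abs(rnorm(300, 2, 1)), 30, 10)
  m <- Matrix::Matrix(base, sparse = TRUE)
  dimnames(m) <- list(paste0("G", 1:30), paste0("c", 1:10))
  p1 <- pca_embed(m, rownames(m), 3L)
  p2 <- pca_embed(m, rownames(m), 3L)
  expect_identical(p1$embedding, p2$embedding)
  # largest-magnitude loading positive
  for (j in 1:3) {
    expect_gt(p1$loadings[which.max(abs(p1$loadings[, j])), j], 0)
  }
  # variance explained non-increasing
  expect_true(all(diff(p1$var_explained) <= 1e-12))
  expect_error(pca_embed(m, rownames(m), 50L), class = "lrx_input_error")
})

test_that("rank-1 data concentrates variance on the first component", {
  t_vals <- seq(0, 1, length.out = 25)
  m <- outer(c(1, 2, 3), t_vals) + 5
  dimnames(m) <- list(paste0("G", 1:3), paste0("c", 1:25))
  p <- pca_embed(Matrix::Matrix(m, sparse = TRUE), rownames(m), 2L)
  expect_gt(p$var_explained[1], 0.999)
})

test_that("k-means recovers separable blobs and is seed-deterministic", {
  set.seed(5)
  blob <- rbind(matrix(rnorm(200, 0), ncol = 2),
                matrix(rnorm(200, 8), ncol = 2))
  rownames(blob) <- paste0("c", 1:200)
  truth <- rep(1:2, each = 100)
  l1 <- cluster_cells(blob, 2L, seed = 3L)
  l2 <- cluster_cells(blob, 2L, seed = 3L)
  expect_identical(l1, l2)
  expect_equal(adjusted_rand_index(l1, truth), 1.0)
  expect_error(cluster_cells(blob, 500L, 1L), class = "lrx_input_error")
})

test_that("clustering the default study separates the target compartments", {
  st <- default_study()
  ann <- default_annotated()
  meta <- ann$cells$cell_meta
  truth <- st$truth$cell_truth
  tc <- truth$true_compartment[match(meta$cell_id, truth$cell_id)]
  qf <- truth$qc_fail[match(meta$cell_id, truth$cell_id)]
  tgt <- tc %in% c("tumor_epithelial", "normal_epithelial",
                   "T_tumor", "T_normal") & qf == "none"
  expect_gte(adjusted_rand_index(meta$cluster[tgt], tc[tgt]), 0.8)
})

test_that("marker scoring assigns compartments and respects the margin rule", {
  st <- default_study()
  ann <- default_annotated()
  meta <- ann$cells$cell_meta
  truth <- st$truth$cell_truth
  tc <- truth$true_compartment[match(meta$cell_id, truth$cell_id)]
  qf <- truth$qc_fail[match(meta$cell_id, truth$cell_id)]
  tgt <- tc %in% c("tumor_epithelial", "normal_epithelial",
                   "T_tumor", "T_normal") & qf == "none"
  expect_gte(mean(meta$cell_type[tgt] == tc[tgt]), 0.95)
  # tumor clusters score highest on the tumor markers
  sc <- ann$annotation$cluster_scores
  tumor_cl <- unique(sc$cluster[sc$assigned == "tumor_epithelial"])
  for (cl in tumor_cl) {
    s <- sc[sc$cluster == cl, ]
    expect_equal(s$compartment[which.max(s$score)], "tumor")
  }
})

test_that("an ambiguous cluster is left unassigned", {
  # marker expression identical everywhere -> all compartment scores tie
  set.seed(8)
  genes <- c("EPCAM", "MDK", "SOX4", "FOLR1", "SFTPD", "AGR3",
             "CD3D", "TRAC", "TRBC2", "OTHER1")
  n <- 60
  m <- matrix(5, length(genes), n,
              dimnames = list(genes, paste0("c", 1:n)))
  m["OTHER1", ] <- rpois(n, 20)
  cells <- toy_cells(m)
  norm <- normalize_log(cells)
  clusters <- stats::setNames(rep(1:2, each = n / 2), colnames(m))
  res <- assign_cell_types(cells, norm, clusters)
  expect_true(all(res$cell_types$cell_type == "unassigned"))
})

test_that("marker scores ignore gene order and unrelated genes", {
  st <- default_study()
  ann <- default_annotated()
  norm <- ann$normalized
  clusters <- stats::setNames(ann$cells$cell_meta$cluster,
                              ann$cells$cell_meta$cell_id)
  base <- assign_cell_types(ann$cells, norm, clusters)
  shuffled <- norm[rev(seq_len(nrow(norm))), ]
  re <- assign_cell_types(ann$cells, shuffled, clusters)
  expect_equal(re$cell_types$cell_type, base$cell_types$cell_type)
})
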