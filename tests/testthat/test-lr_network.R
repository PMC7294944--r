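test_that("spearman matches the classical rank formula and monotone invariance", {
  s <- spearman(1:5, c(3, 1, 2, 5, 4))
  expect_equal(s$rho, 0.6, tolerance = 1e-12)   # 1 - 6*8/(5*24)
  # monotone transform of x gives rho 1
  x <- c(0.2, 1.5, 3.1, 4.8, 9.9, 12)
  expect_equal(spearman(x, exp(x))$rho, 1)
  expect_equal(spearman(x, exp(x))$p_raw, 0)
  # constant vector flagged
  expect_true(is.na(spearman(rep(1, 10), rnorm(10))$rho))
})

test_that("tie-corrected spearman equals a mid-rank Pearson oracle", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- sample(1:8, n, replace = TRUE) + 0.5 * x
    s <- spearman(x, y)
    oracle <- stats::cor(rank(x), rank(y), method = "pearson")
    expect_equal(s$rho, oracle, tolerance = 1e-12)
  }
})

test_that("spearman p matches the t approximation", {
  set.seed(15)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  s <- spearman(x, y)
  tt <- s$rho * sqrt((50 - 2) / (1 - s$rho^2))
  expect_equal(s$p_raw, 2 * stats::pt(abs(tt), 48, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("BH and Holm adjustments match the independent step oracles", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4), tolerance = 1e-12)
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(0.03, "holm"), 0.03)
  set.seed(16)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_pvalues(p, "BH"), stats::p.adjust(p, "BH"),
                 tolerance = 1e-12)
    expect_equal(adjust_pvalues(p, "holm"), stats::p.adjust(p, "holm"),
                 tolerance = 1e-12)
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), class = "lrx_input_error")
})

make_de <- function(genes, dirs) {
  tibble::tibble(gene = genes, lfc = ifelse(dirs == "up", 1, -1),
                 rate_a = 0.5, rate_b = 0.5, stat = 5, df = 2,
                 p_value = ifelse(dirs == "ns", 0.5, 0.01),
                 p_used = ifelse(dirs == "ns", 0.5, 0.01),
                 direction = dirs)
}

test_that("intracellular pairs require concordant direction of both genes", {
  catalog <- lr_catalog(tibble::tibble(ligand = c("L1", "L2", "L3", "L4"),
                                       receptor = c("R1", "R2", "R3", "R4")))
  de <- make_de(c("L1", "R1", "L2", "R2", "L3", "R3"),
                c("up", "up", "up", "down", "down", "down"))
  res <- match_intracellular_pairs(de, catalog)
  expect_equal(res$up$ligand, "L1")
  expect_equal(res$down$ligand, "L3")
  expect_equal(res$n_skipped, 1L)  # L4/R4 absent from the DE table
})

test_that("crosstalk pairs need ligand up in source and receptor up in target", {
  catalog <- lr_catalog(tibble::tibble(ligand = c("L1", "L2"),
                                       receptor = c("R1", "R2")))
  de_src <- make_de(c("L1", "L2", "R1", "R2"), c("up", "up", "ns", "ns"))
  de_tgt <- make_de(c("L1", "L2", "R1", "R2"), c("ns", "ns", "up", "down"))
  res <- match_crosstalk_pairs(de_src, de_tgt, catalog, "tumor_to_T")
  expect_equal(res$pairs$ligand, "L1")
  expect_equal(res$pairs$category, "tumor_to_T")
  expect_error(match_crosstalk_pairs(de_src, de_src, catalog),
               class = "lrx_input_error")
})

test_that("co-expression validation enforces the rho and adjusted-p conjunction", {
  set.seed(17)
  n <- 60
  lat <- rnorm(n)
  expr <- rbind(LA = lat + 0.3 * rnorm(n),
                RA = lat + 0.3 * rnorm(n),       # strongly co-expressed
                LB = rnorm(n), RB = rnorm(n),     # independent
                LC = rep(1, n), RC = rnorm(n))    # constant -> excluded
  colnames(expr) <- sprintf("S%02d", 1:n)
  bulk <- bulk_cohort(expr, tibble::tibble(sample = colnames(expr),
                                           time = 100, event = 1,
                                           stage = "IA"))
  pairs <- tibble::tibble(ligand = c("LA", "LB", "LC", "LX"),
                          receptor = c("RA", "RB", "RC", "RX"))
  out <- validate_coexpression(pairs, bulk, coexpr_config())
  calls <- out$calls
  expect_equal(out$n_absent, 1L)
  expect_true(calls$passed_coexpr[calls$ligand == "LA"])
  expect_false(calls$passed_coexpr[calls$ligand == "LB"])
  expect_false(calls$passed_coexpr[calls$ligand == "LC"])
  # flag always equals the recomputed conjunction
  ok <- !is.na(calls$rho)
  expect_equal(calls$passed_coexpr[ok],
               calls$rho[ok] > 0.4 & calls$rho_p_adj[ok] < 0.05)
  expect_error(validate_coexpression(pairs, bulk,
                                     coexpr_config(min_bulk_samples = 100L)),
               class = "lrx_input_error")
})

test_that("the spearman stage is invariant to monotone transforms of bulk", {
  st <- default_study()
  pairs <- st$truth$pairs[st$truth$pairs$category == "intra_up", ]
  v1 <- validate_coexpression(pairs, st$bulk, coexpr_config())
  bulk2 <- st$bulk
  bulk2$expr <- exp(bulk2$expr / 3)   # strictly increasing transform
  v2 <- validate_coexpression(pairs, bulk2, coexpr_config())
  expect_equal(v1$calls$rho, v2$calls$rho, tolerance = 1e-12)
  expect_equal(v1$calls$passed_coexpr, v2$calls$passed_coexpr)
})

test_that("planted pairs are recovered and decoys controlled on the default study", {
  st <- default_study()
  de <- default_de()
  catalog <- st$truth$catalog
  truth_key <- function(d) paste(d$ligand, d$receptor)
  intra <- match_intracellular_pairs(de$tumor, catalog)
  planted_up <- truth_key(st$truth$pairs[st$truth$pairs$category == "intra_up", ])
  planted_down <- truth_key(st$truth$pairs[st$truth$pairs$category == "intra_down", ])
  expect_true(all(planted_up %in% truth_key(intra$up)))
  expect_true(all(planted_down %in% truth_key(intra$down)))
  # decoy pairs enter at no more than the squared-alpha chance rate (both
  # genes must independently cross alpha in the same direction); allow
  # generous binomial slack on 200 decoys
  decoy_keys <- truth_key(st$truth$pairs[st$truth$pairs$category == "decoy", ])
  n_decoy_in <- sum(decoy_keys %in% c(truth_key(intra$up), truth_key(intra$down)))
  expect_lte(n_decoy_in / length(decoy_keys), 0.05)

  cross <- match_crosstalk_pairs(de$tumor, de$tcell, catalog, "tumor_to_T")
  planted_x <- truth_key(st$truth$pairs[st$truth$pairs$category == "tumor_to_T", ])
  expect_gte(mean(planted_x %in% truth_key(cross$pairs)), 0.9)
  cross_rev <- match_crosstalk_pairs(de$tcell, de$tumor, catalog, "T_to_tumor")
  planted_rev <- truth_key(st$truth$pairs[st$truth$pairs$category == "T_to_tumor", ])
  expect_gte(mean(planted_rev %in% truth_key(cross_rev$pairs)), 0.9)
})
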