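test_that("stage spellings normalize to the IA vs IB-IV dichotomy", {
  cl <- tibble::tibble(sample = paste0("S", 1:6),
                       stage = c("IA", "Stage IA", "ia", "IIIB", "iv", "unknown"))
  rl <- suppressWarnings(make_risk_labels(cl))
  expect_equal(rl$labels$risk,
               c("low_risk", "low_risk", "low_risk", "high_risk", "high_risk"))
  expect_equal(rl$n_excluded, 1L)
  expect_equal(unname(rl$counts), c(3L, 2L))
})

test_that("the stratified split is deterministic, disjoint and balanced", {
  samples <- sprintf("S%03d", 1:100)
  labels <- rep(c("high_risk", "low_risk"), c(60, 40))
  s1 <- split_train_test(samples, labels, 0.75, seed = 5L)
  s2 <- split_train_test(samples, labels, 0.75, seed = 5L)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_setequal(c(s1$train, s1$test), samples)
  # class balance preserved within one sample on each side
  tr_lab <- labels[match(s1$train, samples)]
  expect_lte(abs(mean(tr_lab == "high_risk") - 0.6), 1 / length(s1$train) + 0.02)
})

test_that("a single separating feature yields perfect test F1 and top importance", {
  set.seed(31)
  n <- 120
  genes <- paste0("G", 1:6)
  expr <- matrix(rnorm(6 * n), 6, n, dimnames = list(genes, sprintf("S%03d", 1:n)))
  # a separating feature with a clear margin around the threshold
  # a binary separating feature: boosted trees split exactly at observed
  # values, so held-out samples always land on their correct side
  expr["G3", ] <- sample(rep(c(-1, 1), each = n / 2))
  risk <- ifelse(expr["G3", ] > 0, "high_risk", "low_risk")
  stage <- ifelse(risk == "high_risk", "II", "IA")
  bulk <- bulk_cohort(expr, tibble::tibble(sample = colnames(expr),
                                           time = 100, event = 1, stage = stage))
  rl <- make_risk_labels(bulk$clinical)
  sp <- split_train_test(rl$labels$sample, rl$labels$risk, 0.75, seed = 2L)
  rep_ <- train_risk_model(bulk, genes, rl$labels, sp, nrounds = 50L, seed = 2L)
  expect_equal(rep_$metrics$f1, 1.0)
  expect_equal(rep_$importances$feature[1], "G3")
})

test_that("reported metrics equal metrics recomputed from the confusion matrix", {
  st <- default_study()
  rl <- make_risk_labels(st$bulk$clinical)
  sp <- split_train_test(rl$labels$sample, rl$labels$risk, 0.75, seed = 7L)
  feats <- unique(c(st$truth$pairs$ligand, st$truth$pairs$receptor))
  rep_ <- train_risk_model(st$bulk, feats, rl$labels, sp, seed = 7L)
  cm <- rep_$confusion
  tp <- cm["high_risk", "high_risk"]; fp <- cm["low_risk", "high_risk"]
  fn <- cm["high_risk", "low_risk"]
  expect_equal(rep_$metrics$precision, tp / (tp + fp))
  expect_equal(rep_$metrics$recall, tp / (tp + fn))
  expect_equal(rep_$metrics$f1,
               2 * tp / (2 * tp + fp + fn))
  expect_equal(sum(cm), length(sp$test))
  # reproducible under the same seed
  rep2 <- train_risk_model(st$bulk, feats, rl$labels, sp, seed = 7L)
  expect_identical(rep_$importances, rep2$importances)
  expect_identical(rep_$metrics, rep2$metrics)
})

test_that("the classifier finds planted prognostic signal and loses it on ablation", {
  st <- default_study()
  rl <- make_risk_labels(st$bulk$clinical)
  sp <- split_train_test(rl$labels$sample, rl$labels$risk, 0.75, seed = 3L)
  feats <- unique(c(st$truth$pairs$ligand, st$truth$pairs$receptor))
  rep_full <- train_risk_model(st$bulk, feats, rl$labels, sp, seed = 3L)
  expect_gte(rep_full$metrics$f1, 0.7)
  prog <- st$truth$prognostic$gene
  expect_gte(length(intersect(head(rep_full$importances$feature, 3), prog)), 1)
  # ablation: removing the planted genes weakens the model
  rep_abl <- train_risk_model(st$bulk, setdiff(feats, prog), rl$labels, sp,
                              seed = 3L)
  expect_gte(rep_full$metrics$macro_f1 - rep_abl$metrics$macro_f1, 0.1)
})

test_that("PCA label overlap separates separable classes and not null ones", {
  set.seed(33)
  n <- 200
  genes <- paste0("G", 1:5)
  sep <- matrix(rnorm(5 * n), 5, n, dimnames = list(genes, sprintf("S%03d", 1:n)))
  cls <- rep(c("IA", "II"), each = n / 2)
  sep[, cls == "II"] <- sep[, cls == "II"] + 6
  bulk <- bulk_cohort(sep, tibble::tibble(sample = colnames(sep), time = 10,
                                          event = 1, stage = cls))
  rl <- make_risk_labels(bulk$clinical)
  ov <- pca_label_overlap(bulk, genes, rl$labels)
  expect_gt(ov$silhouette, 0.5)
  # identical distributions: silhouette near zero
  null_ <- matrix(rnorm(5 * n), 5, n, dimnames = dimnames(sep))
  bulk0 <- bulk_cohort(null_, bulk$clinical)
  ov0 <- pca_label_overlap(bulk0, genes, rl$labels)
  expect_lt(abs(ov0$silhouette), 0.1)
})

test_that("an external cohort is dichotomized by predicted risk", {
  st <- default_study()
  rl <- make_risk_labels(st$bulk$clinical)
  sp <- split_train_test(rl$labels$sample, rl$labels$risk, 0.75, seed = 3L)
  feats <- unique(c(st$truth$pairs$ligand, st$truth$pairs$receptor))
  rep_ <- train_risk_model(st$bulk, feats, rl$labels, sp, seed = 3L)
  val <- predict_risk(rep_, st$bulk)
  expect_equal(nrow(val$predictions), nrow(st$bulk$clinical))
  expect_true(all(val$predictions$predicted %in% c("high_risk", "low_risk")))
  expect_false(is.null(val$logrank))
})
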