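#' Stage-based risk labels
#'
#' Normalizes AJCC stage spellings ("Stage IA", "ia" -> "IA") and labels
#' stage IA samples `low_risk`, stages IB-IV `high_risk`. Samples with an
#' unparseable stage are excluded with a warning and counted.
#'
#' @param clinical tibble with `sample` and `stage` columns.
#' @return List with `labels` (tibble: sample, stage_norm, risk),
#'   `n_excluded`, and per-class `counts`.
#' @export
make_risk_labels <- function(clinical) {
  st <- toupper(gsub("\\s+", "", sub("(?i)^stage", "", clinical$stage, perl = TRUE)))
  valid <- c("IA", "IB", "I", "II", "IIA", "IIB", "III", "IIIA", "IIIB",
             "IIIC", "IV", "IVA", "IVB")
  ok <- st %in% valid
  if (any(!ok)) {
    rlang::warn(sprintf("%d sample(s) with unparseable stage excluded", sum(!ok)))
  }
  labels <- tibble(sample = clinical$sample[ok], stage_norm = st[ok]) |>
    mutate(risk = ifelse(.data$stage_norm == "IA", "low_risk", "high_risk"))
  list(labels = labels, n_excluded = sum(!ok),
       counts = c(low_risk = sum(labels$risk == "low_risk"),
                  high_risk = sum(labels$risk == "high_risk")))
}

#' Stratified train/test split
#'
#' Random split at the requested ratio, stratified by label, seeded.
#'
#' @param samples character vector of sample ids.
#' @param labels character vector of class labels (parallel to `samples`).
#' @param train_frac training fraction (default 0.75, i.e. 3:1).
#' @param seed RNG seed.
#' @return List with disjoint, exhaustive `train` and `test` id vectors.
#' @export
split_train_test <- function(samples, labels, train_frac = 0.75, seed = 1L) {
  if (length(samples) < 8) stop_input("need at least 8 samples to split")
  assert_fraction(train_frac, "train_frac", 0.05, 0.95)
  with_seed(child_seed(seed, 4L), {
    train <- character(0)
    for (cl in sort(unique(labels))) {
      ids <- samples[labels == cl]
      n_tr <- round(length(ids) * train_frac)
      train <- c(train, sample(ids, n_tr))
    }
    test <- setdiff(samples, train)
    tr_lab <- labels[samples %in% train]
    te_lab <- labels[samples %in% test]
    if (length(unique(tr_lab)) < length(unique(labels)) ||
        length(unique(te_lab)) < length(unique(labels))) {
      stop_input("a class is absent from train or test; use a different seed or ratio")
    }
    list(train = train, test = test)
  })
}

#' Train and evaluate the gradient-boosted risk classifier
#'
#' Fits an XGBoost binary classifier (`high_risk` = positive class) on the
#' bulk expression of the supplied feature genes, evaluated on the held-out
#' test set. Reports precision/recall/F1 for the high-risk class, macro
#' averages, the confusion matrix, and gain-based feature importances
#' (ties broken by feature name), all reproducible under the fixed seed and
#' single-threaded training.
#'
#' @param bulk a [bulk_cohort()].
#' @param feature_genes genes used as features (e.g. all LR pair-call
#'   genes); absent genes are dropped.
#' @param labels tibble from [make_risk_labels()]`$labels`.
#' @param split list from [split_train_test()].
#' @param nrounds,max_depth,eta boosting hyperparameters (defaults 300 /
#'   3 / 0.1).
#' @param seed RNG seed for training.
#' @return A `risk_model_report` list: metrics, confusion matrix,
#'   importances, predictions, hyperparameters, and the fitted booster.
#' @export
train_risk_model <- function(bulk, feature_genes, labels, split,
                             nrounds = 300L, max_depth = 3L, eta = 0.1,
                             seed = 1L) {
  feature_genes <- intersect(unique(toupper(feature_genes)), rownames(bulk$expr))
  if (length(feature_genes) == 0) stop_input("no feature genes present in bulk")
  lab <- stats::setNames(labels$risk, labels$sample)
  tr <- intersect(split$train, labels$sample)
  te <- intersect(split$test, labels$sample)
  y_tr <- as.integer(lab[tr] == "high_risk")
  y_te <- as.integer(lab[te] == "high_risk")
  if (length(unique(y_tr)) < 2) stop_input("training set has a single class")
  x_tr <- t(bulk$expr[feature_genes, tr, drop = FALSE])
  x_te <- t(bulk$expr[feature_genes, te, drop = FALSE])
  dtrain <- xgboost::xgb.DMatrix(x_tr, label = y_tr, nthread = 1)
  params <- xgboost::xgb.params(objective = "binary:logistic",
                                max_depth = max_depth, learning_rate = eta,
                                nthread = 1, seed = child_seed(seed, 5L))
  booster <- xgboost::xgb.train(params, dtrain, nrounds = nrounds, verbose = 0)
  prob <- predict(booster, xgboost::xgb.DMatrix(x_te, nthread = 1))
  pred <- as.integer(prob >= 0.5)
  cm <- confusion_2x2(y_te, pred)
  metrics <- classification_metrics(cm)

  imp_raw <- xgboost::xgb.importance(model = booster)
  imp <- tibble(feature = character(0), gain = numeric(0))
  if (!is.null(imp_raw) && nrow(imp_raw)) {
    imp <- tibble(feature = imp_raw$Feature, gain = imp_raw$Gain) |>
      arrange(dplyr::desc(.data$gain), .data$feature) |>
      mutate(rank = dplyr::row_number())
  }
  structure(list(
    metrics = metrics,
    confusion = cm,
    importances = imp,
    predictions = tibble(sample = te, prob_high = prob,
                         predicted = ifelse(pred == 1, "high_risk", "low_risk"),
                         actual = ifelse(y_te == 1, "high_risk", "low_risk")),
    hyperparams = list(nrounds = nrounds, max_depth = max_depth, eta = eta,
                       seed = seed, n_features = length(feature_genes)),
    feature_genes = feature_genes,
    booster = booster
  ), class = "risk_model_report")
}

# rows = actual (0 low, 1 high), cols = predicted
confusion_2x2 <- function(actual, predicted) {
  matrix(c(sum(actual == 0 & predicted == 0), sum(actual == 0 & predicted == 1),
           sum(actual == 1 & predicted == 0), sum(actual == 1 & predicted == 1)),
         nrow = 2, byrow = TRUE,
         dimnames = list(actual = c("low_risk", "high_risk"),
                         predicted = c("low_risk", "high_risk")))
}

classification_metrics <- function(cm) {
  prf <- function(tp, fp, fn) {
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  }
  hi <- prf(cm["high_risk", "high_risk"], cm["low_risk", "high_risk"],
            cm["high_risk", "low_risk"])
  lo <- prf(cm["low_risk", "low_risk"], cm["high_risk", "low_risk"],
            cm["low_risk", "high_risk"])
  list(precision = unname(hi["precision"]), recall = unname(hi["recall"]),
       f1 = unname(hi["f1"]),
       macro_precision = unname((hi["precision"] + lo["precision"]) / 2),
       macro_recall = unname((hi["recall"] + lo["recall"]) / 2),
       macro_f1 = unname((hi["f1"] + lo["f1"]) / 2),
       accuracy = sum(diag(cm)) / sum(cm))
}

#' Predict risk labels for an external cohort
#'
#' Applies a fitted risk model to a new bulk cohort (e.g. one without stage
#' information) and optionally compares the survival of the predicted
#' groups with a log-rank test, the validation strategy for cohorts lacking
#' stage labels.
#'
#' @param report a `risk_model_report`.
#' @param bulk a [bulk_cohort()].
#' @param run_logrank compare predicted-group survival (default TRUE).
#' @return List with `predictions` tibble and, when requested, `logrank`.
#' @export
predict_risk <- function(report, bulk, run_logrank = TRUE) {
  genes <- report$feature_genes
  miss <- setdiff(genes, rownames(bulk$expr))
  if (length(miss)) {
    stop_input(sprintf("%d model feature(s) absent from cohort", length(miss)))
  }
  x <- t(bulk$expr[genes, bulk$clinical$sample, drop = FALSE])
  prob <- predict(report$booster, xgboost::xgb.DMatrix(x, nthread = 1))
  preds <- tibble(sample = bulk$clinical$sample, prob_high = prob,
                  predicted = ifelse(prob >= 0.5, "high_risk", "low_risk"))
  out <- list(predictions = preds)
  if (run_logrank && length(unique(preds$predicted)) == 2) {
    cl <- bulk$clinical
    hi <- cl[preds$predicted == "high_risk", ]
    lo <- cl[preds$predicted == "low_risk", ]
    out$logrank <- logrank(hi$time, hi$event, lo$time, lo$event)
  }
  out
}

#' PCA overlap of risk labels
#'
#' Embeds samples by PCA on the supplied genes' expression and summarizes
#' how separable the two risk groups are in PC1-2 with the mean silhouette
#' width (near 0 = mixed groups, as observed for stage-derived labels).
#'
#' @param bulk a [bulk_cohort()].
#' @param feature_genes genes to embed on.
#' @param labels tibble from [make_risk_labels()]`$labels`.
#' @return List with `coords` (tibble: sample, PC1, PC2, risk),
#'   `silhouette` (mean width), `var_explained`.
#' @export
pca_label_overlap <- function(bulk, feature_genes, labels) {
  feature_genes <- intersect(unique(toupper(feature_genes)), rownames(bulk$expr))
  ids <- intersect(labels$sample, colnames(bulk$expr))
  if (length(ids) < 3) stop_input("need at least 3 labeled samples")
  emb <- pca_embed(methods::as(Matrix::Matrix(bulk$expr[feature_genes, ids,
                                                        drop = FALSE],
                                              sparse = TRUE), "CsparseMatrix"),
                   feature_genes, n_pcs = 2L)
  risk <- labels$risk[match(ids, labels$sample)]
  sil <- NA_real_
  if (length(unique(risk)) == 2) {
    d <- stats::dist(emb$embedding)
    sil <- mean(cluster::silhouette(as.integer(factor(risk)), d)[, "sil_width"])
  }
  list(coords = tibble(sample = ids,
                       PC1 = emb$embedding[, 1], PC2 = emb$embedding[, 2],
                       risk = risk),
       silhouette = sil,
       var_explained = emb$var_explained)
}

#' @export
print.risk_model_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<risk_model_report> high-risk precision %.3f / recall %.3f / F1 %.3f (macro F1 %.3f)\n",
              m$precision, m$recall, m$f1, m$macro_f1))
  cat("  top features:",
      paste(head(x$importances$feature, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.risk_model_report <- function(x, ...) x$importances

#' @export
glance.risk_model_report <- function(x, ...) {
  as_tibble(x$metrics)
}
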