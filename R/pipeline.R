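#' Default run configuration
#'
#' Assembles the full pipeline configuration: input paths, stage configs
#' and the global seed. Every threshold used anywhere in the pipeline is
#' surfaced here. `config` may also be loaded from a YAML file with
#' [read_run_config()].
#'
#' @param sc_dir 10x triplet directory.
#' @param catalog_path LR catalog TSV.
#' @param bulk_expr_path,bulk_clinical_path bulk cohort TSVs.
#' @param outdir output directory.
#' @param seed global seed propagated to every stochastic stage.
#' @param qc,annotate,coexpr stage configuration objects.
#' @param de_alpha,de_adjust DE call threshold and adjustment
#'   (`"none"`/`"BH"`).
#' @param survival_alpha survival-screen threshold.
#' @param model hyperparameter list (nrounds, max_depth, eta, train_frac).
#' @return A list of class `run_config`.
#' @export
run_config <- function(sc_dir, catalog_path, bulk_expr_path,
                       bulk_clinical_path, outdir,
                       seed = 1L,
                       qc = qc_config(),
                       annotate = annotation_config(),
                       de_alpha = 0.05, de_adjust = "none",
                       coexpr = coexpr_config(),
                       survival_alpha = 0.05,
                       model = list(nrounds = 300L, max_depth = 3L,
                                    eta = 0.1, train_frac = 0.75)) {
  structure(list(sc_dir = sc_dir, catalog_path = catalog_path,
                 bulk_expr_path = bulk_expr_path,
                 bulk_clinical_path = bulk_clinical_path, outdir = outdir,
                 seed = assert_count(seed, "seed", 0L), qc = qc,
                 annotate = annotate, de_alpha = de_alpha,
                 de_adjust = de_adjust, coexpr = coexpr,
                 survival_alpha = survival_alpha, model = model),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys `paths` (sc_dir, catalog, bulk_expr, bulk_clinical,
#' outdir), `seed`, and optional stage blocks `qc`, `annotate`, `de`,
#' `coexpr`, `survival`, `model` whose entries override the defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  p <- y$paths
  if (is.null(p)) stop_format("config must have a `paths` block")
  cfg <- run_config(
    sc_dir = p$sc_dir, catalog_path = p$catalog,
    bulk_expr_path = p$bulk_expr, bulk_clinical_path = p$bulk_clinical,
    outdir = p$outdir, seed = y$seed %||% 1L,
    qc = do.call(qc_config, y$qc %||% list()),
    annotate = do.call(annotation_config, y$annotate %||% list()),
    de_alpha = y$de$alpha %||% 0.05, de_adjust = y$de$adjust %||% "none",
    coexpr = do.call(coexpr_config, y$coexpr %||% list()),
    survival_alpha = y$survival$alpha %||% 0.05)
  for (nm in names(y$model %||% list())) cfg$model[[nm]] <- y$model[[nm]]
  cfg
}

#' Write a synthetic dataset to disk
#'
#' Generates the seeded synthetic study ([simulate_sc()] +
#' [simulate_bulk_clinical()]) and writes the 10x triplet, the LR catalog,
#' the bulk expression and clinical TSVs, and `truth.json`.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @param force overwrite an existing directory (default FALSE).
#' @return Invisibly, the in-memory `list(cells, truth, bulk)`.
#' @export
simulate_dataset <- function(config = sim_config(), dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    stop_input(sprintf("output directory %s is non-empty; use force = TRUE", dir))
  }
  sim <- simulate_sc(config)
  bulk <- simulate_bulk_clinical(config, sim$truth)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_10x_triplet(sim$cells, file.path(dir, "sc"))
  readr::write_tsv(as_tibble(sim$truth$catalog)[, c("ligand", "receptor")],
                   file.path(dir, "lr_catalog.tsv"))
  write_bulk(bulk, file.path(dir, "bulk_expr.tsv"),
             file.path(dir, "clinical.tsv"))
  truth_json <- list(
    pairs = sim$truth$pairs,
    gene_effects = sim$truth$gene_effects,
    prognostic = sim$truth$prognostic,
    cell_truth = sim$truth$cell_truth,
    seed = config$seed
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(list(cells = sim$cells, truth = sim$truth, bulk = bulk))
}

#' Run the full pipeline
#'
#' Executes io -> QC/annotation -> hurdle DE (two contrasts) -> LR pair
#' inference (four categories, with bulk co-expression validation) ->
#' survival screen -> risk model, writing every stage table plus a JSON run
#' manifest with input/output counts at each stage.
#'
#' @param config a `run_config` (or YAML path).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  for (p in c(config$sc_dir, config$catalog_path, config$bulk_expr_path,
              config$bulk_clinical_path)) {
    if (!file.exists(p)) stop_input(sprintf("input path does not exist: %s", p))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  cells <- read_10x_triplet(config$sc_dir)
  catalog <- read_lr_catalog(config$catalog_path)
  bulk <- read_bulk(config$bulk_expr_path, config$bulk_clinical_path)

  ann <- annotate_cells(cells, config$qc, config$annotate)
  meta <- ann$cells$cell_meta

  grp <- function(type) meta$cell_id[meta$cell_type == type]
  contrasts <- list(
    tumor_vs_epithelial = list(a = grp("tumor_epithelial"),
                               b = grp("normal_epithelial")),
    Ttumor_vs_Tnormal = list(a = grp("T_tumor"), b = grp("T_normal")))
  de <- lapply(contrasts, function(ct) {
    if (length(ct$a) == 0 || length(ct$b) == 0) {
      stop_input("an annotated compartment is empty; cannot run DE")
    }
    call_direction(hurdle_test(ann$normalized, ct$a, ct$b),
                   alpha = config$de_alpha, adjust = config$de_adjust)
  })

  intra_tumor <- match_intracellular_pairs(de$tumor_vs_epithelial, catalog)
  intra_t <- match_intracellular_pairs(de$Ttumor_vs_Tnormal, catalog)
  cross_t2T <- match_crosstalk_pairs(de$tumor_vs_epithelial,
                                     de$Ttumor_vs_Tnormal, catalog,
                                     "tumor_to_T")
  cross_T2t <- match_crosstalk_pairs(de$Ttumor_vs_Tnormal,
                                     de$tumor_vs_epithelial, catalog,
                                     "T_to_tumor")
  categories <- list(
    intra_up = mutate(intra_tumor$up, category = "intra_up"),
    intra_down = mutate(intra_tumor$down, category = "intra_down"),
    intra_T_up = mutate(intra_t$up, category = "intra_T_up"),
    intra_T_down = mutate(intra_t$down, category = "intra_T_down"),
    tumor_to_T = cross_t2T$pairs,
    T_to_tumor = cross_T2t$pairs)
  validated <- lapply(categories, function(prs) {
    if (nrow(prs) == 0) return(list(calls = prs, n_absent = 0L))
    validate_coexpression(prs, bulk, config$coexpr)
  })
  all_calls <- bind_rows(lapply(validated, function(v) as_tibble(v$calls)))
  passed <- all_calls |> filter(.data$passed_coexpr)

  pair_genes <- unique(c(passed$ligand, passed$receptor))
  screen <- survival_screen(pair_genes, bulk, config$survival_alpha)

  rl <- make_risk_labels(bulk$clinical)
  split <- split_train_test(rl$labels$sample, rl$labels$risk,
                            config$model$train_frac %||% 0.75, config$seed)
  model_genes <- unique(c(all_calls$ligand, all_calls$receptor))
  model <- train_risk_model(bulk, model_genes, rl$labels, split,
                            nrounds = config$model$nrounds %||% 300L,
                            max_depth = config$model$max_depth %||% 3L,
                            eta = config$model$eta %||% 0.1,
                            seed = config$seed)
  overlap <- pca_label_overlap(bulk, model_genes, rl$labels)

  # stage tables
  out_tables <- c(
    list(cell_annotation = meta,
         cluster_scores = ann$annotation$cluster_scores,
         de_tumor_vs_epithelial = de$tumor_vs_epithelial,
         de_Ttumor_vs_Tnormal = de$Ttumor_vs_Tnormal,
         survival_screen = screen$results,
         model_importances = model$importances,
         model_predictions = model$predictions),
    stats::setNames(lapply(validated, function(v) as_tibble(v$calls)),
                    paste0("pairs_", names(validated))))
  write_results(out_tables, config$outdir)

  manifest <- list(
    seed = config$seed,
    qc = as.list(attr(ann$cells, "qc_removed")),
    n_cells_annotated = nrow(meta),
    cells_per_type = as.list(table(meta$cell_type)),
    deg_counts = lapply(de, function(d) list(
      up = sum(d$direction == "up"), down = sum(d$direction == "down"),
      up_bh = sum(adjust_pvalues(d$p_value, "BH") < config$de_alpha & d$lfc > 0),
      down_bh = sum(adjust_pvalues(d$p_value, "BH") < config$de_alpha & d$lfc < 0))),
    pairs = lapply(names(validated), function(nm) list(
      category = nm,
      candidates = nrow(validated[[nm]]$calls),
      validated = sum(validated[[nm]]$calls[["passed_coexpr"]] %||% FALSE))),
    survival = list(tested = nrow(screen$results),
                    significant = sum(screen$results$significant),
                    unsplittable = length(screen$unsplittable)),
    risk_labels = as.list(rl$counts),
    model = c(model$metrics, list(hyperparams = model$hyperparams,
                                  top_features = head(model$importances$feature, 10))),
    pca_overlap_silhouette = overlap$silhouette
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(annotation = ann, de = de, pairs = validated,
                 pair_calls = all_calls, survival = screen, model = model,
                 overlap = overlap, manifest = manifest,
                 outdir = config$outdir))
}
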