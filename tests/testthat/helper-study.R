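# shared fixtures, built once per test run and cached

.study_cache <- new.env(parent = emptyenv())

# the default synthetic study used by truth-recovery tests
default_study <- function() {
  if (is.null(.study_cache$study)) {
    cfg <- sim_config(seed = 101L)
    sim <- simulate_sc(cfg)
    bulk <- simulate_bulk_clinical(cfg, sim$truth)
    .study_cache$study <- list(cfg = cfg, cells = sim$cells,
                               truth = sim$truth, bulk = bulk)
  }
  .study_cache$study
}

default_annotated <- function() {
  if (is.null(.study_cache$ann)) {
    .study_cache$ann <- annotate_cells(default_study()$cells)
  }
  .study_cache$ann
}

# direction-labeled DE tables for the two pipeline contrasts
default_de <- function() {
  if (is.null(.study_cache$de)) {
    ann <- default_annotated()
    meta <- ann$cells$cell_meta
    grp <- function(type) meta$cell_id[meta$cell_type == type]
    .study_cache$de <- list(
      tumor = call_direction(hurdle_test(ann$normalized,
                                         grp("tumor_epithelial"),
                                         grp("normal_epithelial"))),
      tcell = call_direction(hurdle_test(ann$normalized,
                                         grp("T_tumor"), grp("T_normal"))))
  }
  .study_cache$de
}

# a small cell_matrix built by hand for cheap unit tests
toy_cells <- function(counts) {
  cell_matrix(counts,
              tibble::tibble(cell_id = colnames(counts),
                             sample = "S1", patient = "P1",
                             tissue = "tumor"))
}

# one full pipeline execution on the default study, cached across files.
# writes the dataset and results under a session-lived temp dir.
cached_pipeline_run <- function() {
  if (is.null(.study_cache$pipeline_run)) {
    base <- file.path(tempdir(), "lrx-pipeline-fixture")
    ds_dir <- file.path(base, "ds"); out_dir <- file.path(base, "out")
    simulate_dataset(default_study()$cfg, ds_dir, force = TRUE)
    res <- run_all(run_config(file.path(ds_dir, "sc"),
                              file.path(ds_dir, "lr_catalog.tsv"),
                              file.path(ds_dir, "bulk_expr.tsv"),
                              file.path(ds_dir, "clinical.tsv"),
                              out_dir, seed = 101L))
    .study_cache$pipeline_run <- list(res = res, ds_dir = ds_dir,
                                      out_dir = out_dir)
  }
  .study_cache$pipeline_run
}

subset_cells_for_test <- function(cells, keep) {
  lrcrosstalk:::subset_cells(cells, keep)
}

adjusted_rand_index <- function(a, b) {
  tt <- table(a, b)
  n <- sum(tt)
  sij <- sum(choose(tt, 2))
  si <- sum(choose(rowSums(tt), 2))
  sj <- sum(choose(colSums(tt), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}
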