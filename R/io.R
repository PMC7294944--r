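#' Ligand-receptor catalog
#'
#' An ordered table of (ligand, receptor) gene-symbol pairs, FANTOM5-style.
#' Symbols are uppercased; duplicate ordered pairs are rejected.
#'
#' @param pairs data frame with columns `ligand` and `receptor`.
#' @return A tibble of class `lr_catalog` with columns ligand, receptor.
#' @export
lr_catalog <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (!all(c("ligand", "receptor") %in% names(pairs))) {
    stop_format("catalog needs `ligand` and `receptor` columns")
  }
  pairs <- pairs |>
    mutate(ligand = toupper(.data$ligand), receptor = toupper(.data$receptor))
  if (any(!nzchar(pairs$ligand)) || any(!nzchar(pairs$receptor))) {
    stop_format("catalog gene symbols must be non-empty")
  }
  key <- paste(pairs$ligand, pairs$receptor, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_format(sprintf("duplicate ligand-receptor pair at row %d: %s-%s",
                        dup[1], pairs$ligand[dup[1]], pairs$receptor[dup[1]]))
  }
  class(pairs) <- c("lr_catalog", class(pairs))
  pairs
}

#' Read a 10x Genomics triplet directory
#'
#' Reads `matrix.mtx`, `features.tsv` and `barcodes.tsv` (plain or `.gz`)
#' plus a `cell_metadata.tsv` table. MTX coordinates are 1-based on disk and
#' mapped to the internal 0-based convention; genes are MTX rows. Duplicate
#' gene symbols are disambiguated by suffixing `.1`, `.2`, ... in file order.
#'
#' @param dir_path directory containing the triplet files.
#' @param metadata optional path to the cell metadata TSV (default
#'   `cell_metadata.tsv` inside `dir_path`).
#' @return A [cell_matrix()].
#' @export
read_10x_triplet <- function(dir_path,
                             metadata = file.path(dir_path, "cell_metadata.tsv")) {
  find1 <- function(stem) {
    for (f in c(file.path(dir_path, stem), file.path(dir_path, paste0(stem, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    stop_format(sprintf("missing %s(.gz) in %s", stem, dir_path))
  }
  m <- Matrix::readMM(find1("matrix.mtx"))
  feats <- readr::read_tsv(find1("features.tsv"), col_names = FALSE,
                           show_col_types = FALSE)
  bcs <- readr::read_tsv(find1("barcodes.tsv"), col_names = FALSE,
                         show_col_types = FALSE)
  if (nrow(feats) != nrow(m)) {
    stop_format(sprintf("features.tsv has %d rows but matrix has %d gene rows",
                        nrow(feats), nrow(m)))
  }
  if (nrow(bcs) != ncol(m)) {
    stop_format(sprintf("barcodes.tsv has %d rows but matrix has %d cell columns",
                        nrow(bcs), ncol(m)))
  }
  symbols <- make_unique_symbols(toupper(feats[[1]]))
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  dimnames(m) <- list(symbols, bcs[[1]])
  if (!file.exists(metadata)) {
    stop_format(sprintf("missing cell metadata table: %s", metadata))
  }
  meta <- readr::read_tsv(metadata, show_col_types = FALSE)
  cell_matrix(m, meta)
}

# GENEA, GENEA -> GENEA, GENEA.1 (file order)
make_unique_symbols <- function(x) {
  out <- x
  dup <- duplicated(x)
  if (any(dup)) {
    for (s in unique(x[dup])) {
      idx <- which(x == s)
      out[idx[-1]] <- paste0(s, ".", seq_along(idx[-1]))
    }
  }
  out
}

#' Write a cell_matrix as a 10x triplet directory
#'
#' Writes `matrix.mtx` (1-based coordinates), `features.tsv`,
#' `barcodes.tsv` and `cell_metadata.tsv`.
#'
#' @param cells a [cell_matrix()].
#' @param dir_path output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_10x_triplet <- function(cells, dir_path) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cells$counts, file.path(dir_path, "matrix.mtx"))
  readr::write_tsv(tibble(symbol = rownames(cells$counts)),
                   file.path(dir_path, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(barcode = colnames(cells$counts)),
                   file.path(dir_path, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(cells$cell_meta, file.path(dir_path, "cell_metadata.tsv"))
  invisible(dir_path)
}

#' Read a ligand-receptor catalog TSV
#'
#' Two-column TSV with header `ligand`, `receptor`; file order is preserved.
#'
#' @param path TSV path.
#' @return An [lr_catalog()].
#' @export
read_lr_catalog <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  lr_catalog(tab)
}

#' Read a bulk cohort (expression TSV + clinical TSV)
#'
#' The expression table is genes x samples with a leading `gene` column; the
#' clinical table needs `sample`, `time`, `event`, `stage`. Validation
#' errors report the offending row.
#'
#' @param path_expr expression TSV path.
#' @param path_clinical clinical TSV path.
#' @return A [bulk_cohort()].
#' @export
read_bulk <- function(path_expr, path_clinical) {
  ex <- readr::read_tsv(path_expr, show_col_types = FALSE)
  if (names(ex)[1] != "gene") {
    stop_format("bulk expression TSV must start with a `gene` column")
  }
  mat <- as.matrix(ex[, -1, drop = FALSE])
  rownames(mat) <- ex$gene
  if (!is.numeric(mat)) stop_format("bulk expression values must be numeric")
  cl <- readr::read_tsv(path_clinical, show_col_types = FALSE,
                        col_types = readr::cols(sample = "c", stage = "c"))
  bulk_cohort(mat, cl)
}

#' Write result tables to a directory
#'
#' Writes each table in `tables` as `<name>.tsv` with a fixed column order.
#'
#' @param tables named list of data frames.
#' @param dir output directory (created if needed).
#' @return Invisible character vector of written paths.
#' @export
write_results <- function(tables, dir) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop_input("`tables` must be a fully named list")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(as_tibble(tables[[nm]]), p)
    p
  }, character(1))
  invisible(paths)
}

#' Write a bulk cohort to TSV files
#'
#' @param bulk a [bulk_cohort()].
#' @param path_expr,path_clinical output TSV paths.
#' @return Invisible NULL.
#' @export
write_bulk <- function(bulk, path_expr, path_clinical) {
  ex <- bind_cols(tibble(gene = rownames(bulk$expr)),
                  as_tibble(bulk$expr, .name_repair = "minimal"))
  readr::write_tsv(ex, path_expr)
  readr::write_tsv(bulk$clinical, path_clinical)
  invisible(NULL)
}
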