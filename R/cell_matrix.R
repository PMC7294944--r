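#' Single-cell count container
#'
#' A light container for sparse gene-by-cell UMI counts plus per-cell
#' metadata. Gene symbols are the matrix rownames (uppercased, unique),
#' cell ids the colnames. `cell_meta` is a tibble keyed by `cell_id` with
#' at least `sample`, `patient` and `tissue` (one of `"tumor"`, `"normal"`),
#' and gains QC statistics (`n_genes_detected`, `mito_fraction`,
#' `ribo_fraction`), `cluster` and `cell_type` columns as the pipeline runs.
#'
#' @param counts sparse (or dense) numeric matrix, genes x cells, with
#'   non-negative integer entries; rownames are gene symbols, colnames cell ids.
#' @param cell_meta data frame with one row per cell.
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_meta) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_input("`counts` must have gene symbols as rownames and cell ids as colnames")
  }
  rownames(counts) <- toupper(rownames(counts))
  if (anyDuplicated(rownames(counts))) {
    stop_input("gene symbols must be unique after uppercasing")
  }
  if (anyDuplicated(colnames(counts))) stop_input("cell ids must be unique")
  if (any(counts@x < 0)) stop_input("counts must be non-negative")
  cell_meta <- as_tibble(cell_meta)
  need <- c("cell_id", "sample", "tissue")
  miss <- setdiff(need, names(cell_meta))
  if (length(miss)) {
    stop_input(paste0("cell_meta is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(cell_meta$tissue %in% c("tumor", "normal"))) {
    stop_input("tissue must be 'tumor' or 'normal'")
  }
  if (!setequal(cell_meta$cell_id, colnames(counts)) ||
      nrow(cell_meta) != ncol(counts)) {
    stop_input("cell_meta$cell_id must match the matrix columns one-to-one")
  }
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell_id), ]
  structure(list(counts = counts, cell_meta = cell_meta), class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  samples: %d (%d tumor / %d normal cells)\n",
              length(unique(x$cell_meta$sample)),
              sum(x$cell_meta$tissue == "tumor"),
              sum(x$cell_meta$tissue == "normal")))
  if (!is.null(x$cell_meta[["cell_type"]])) {
    tt <- table(x$cell_meta$cell_type)
    cat("  cell types:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Gene symbols of a cell_matrix
#' @param x a `cell_matrix`.
#' @return Character vector of gene symbols.
#' @export
gene_symbols <- function(x) rownames(x$counts)

#' Cell ids of a cell_matrix
#' @param x a `cell_matrix`.
#' @return Character vector of cell ids.
#' @export
cell_ids <- function(x) colnames(x$counts)

# subset cells (logical/integer/character index), keeping metadata aligned
subset_cells <- function(x, keep) {
  counts <- x$counts[, keep, drop = FALSE]
  meta <- x$cell_meta[match(colnames(counts), x$cell_meta$cell_id), ]
  out <- x
  out$counts <- counts
  out$cell_meta <- meta
  out
}
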