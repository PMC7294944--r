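#' Annotation configuration
#'
#' @param n_hvg number of highly variable genes used for embedding.
#' @param n_pcs number of principal components.
#' @param k_clusters number of k-means clusters.
#' @param assignment_margin minimum marker-score gap (z-score scale) between
#'   the best and runner-up compartment for a cluster to be typed.
#' @param cluster_seed seed for k-means initialization.
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(n_hvg = 1500L, n_pcs = 20L, k_clusters = 9L,
                              assignment_margin = 0.25, cluster_seed = 42L) {
  structure(list(n_hvg = assert_count(n_hvg, "n_hvg"),
                 n_pcs = assert_count(n_pcs, "n_pcs"),
                 k_clusters = assert_count(k_clusters, "k_clusters", min = 2L),
                 assignment_margin = assert_fraction(assignment_margin,
                                                     "assignment_margin", 0, 10),
                 cluster_seed = assert_count(cluster_seed, "cluster_seed", 0L)),
            class = "annotation_config")
}

#' Marker panel
#'
#' Maps each compartment to its marker genes. Defaults are the LUAD panel:
#' tumor EPCAM/MDK/SOX4, normal (alveolar) epithelial FOLR1/SFTPD/AGR3,
#' T cells CD3D/TRAC/TRBC2.
#'
#' @param tumor,epithelial,T character vectors of marker gene symbols.
#' @return A named list of class `marker_panel`.
#' @export
marker_panel <- function(tumor = c("EPCAM", "MDK", "SOX4"),
                         epithelial = c("FOLR1", "SFTPD", "AGR3"),
                         T = c("CD3D", "TRAC", "TRBC2")) {
  panel <- list(tumor = toupper(tumor), epithelial = toupper(epithelial),
                T = toupper(T))
  if (any(lengths(panel) == 0)) stop_input("marker sets must be non-empty")
  all_g <- unlist(panel)
  if (anyDuplicated(all_g)) stop_input("marker sets must be pairwise disjoint")
  structure(panel, class = "marker_panel")
}

#' PCA embedding of cells
#'
#' Subsets to the supplied genes, scales each gene to zero mean and unit
#' variance (values clipped at +/-10), and computes a deterministic PCA.
#' The sign convention makes the largest-magnitude loading of each
#' component positive.
#'
#' @param normalized genes x cells normalized matrix.
#' @param genes genes to embed on (e.g. from [select_hvg()]).
#' @param n_pcs number of components.
#' @return List with `embedding` (cells x n_pcs), `loadings`,
#'   `var_explained`.
#' @export
pca_embed <- function(normalized, genes, n_pcs = 20L) {
  genes <- intersect(genes, rownames(normalized))
  x <- t(as.matrix(normalized[genes, , drop = FALSE]))  # cells x genes
  if (n_pcs > min(dim(x))) {
    stop_input(sprintf("n_pcs = %d exceeds min(cells, genes) = %d",
                       n_pcs, min(dim(x))))
  }
  sds <- apply(x, 2, sd)
  keep <- sds > 0
  x <- scale(x[, keep, drop = FALSE])
  x[x > 10] <- 10
  x[x < -10] <- -10
  pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)
  # sign convention: largest-|loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(embedding = pc$x[, seq_len(n_pcs), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_pcs), drop = FALSE],
       var_explained = ve[seq_len(n_pcs)])
}

#' Cluster cells by k-means with k-means++ initialization
#'
#' Runs k-means (Lloyd) from 50 greedy k-means++ seedings at a fixed seed and
#' keeps the solution with the lowest total within-cluster sum of squares.
#' Cluster labels are relabeled 1..k by decreasing cluster size.
#'
#' @param embedding cells x dims matrix from [pca_embed()].
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param n_restarts independent k-means++ restarts.
#' @return Integer vector of cluster labels (named by cell id).
#' @export
cluster_cells <- function(embedding, k = 9L, seed = 42L, n_restarts = 50L) {
  k <- assert_count(k, "k", 2L)
  if (k > nrow(embedding)) stop_input("k exceeds the number of cells")
  with_seed(child_seed(seed, 3L), {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      centers <- kmeanspp_init(embedding, k)
      fit <- suppressWarnings(
        kmeans(embedding, centers = centers, iter.max = 100,
               algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    sizes <- table(best$cluster)
    # order by decreasing size, ties by old label for determinism
    new_order <- order(-as.integer(sizes), as.integer(names(sizes)))
    relabel <- integer(k)
    relabel[as.integer(names(sizes))[new_order]] <- seq_len(k)
    labels <- relabel[best$cluster]
    names(labels) <- rownames(embedding)
    labels
  })
}

# greedy k-means++ seeding: first center uniform; each subsequent center
# drawn as the best of 2 + floor(log(k)) candidates sampled proportional
# to squared distance to the nearest chosen center (the candidate that
# minimizes the resulting potential wins). Much better than plain ++ at
# seeding small, distant clusters.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  n_cand <- 2L + as.integer(floor(log(k)))
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in 2:k) {
    cand <- sample.int(n, n_cand, prob = d2 / sum(d2))
    best_pot <- Inf; best_d2 <- NULL; best_i <- cand[1]
    for (ci in cand) {
      nd2 <- pmin(d2, rowSums(sweep(x, 2, x[ci, ])^2))
      pot <- sum(nd2)
      if (pot < best_pot) { best_pot <- pot; best_d2 <- nd2; best_i <- ci }
    }
    centers[j, ] <- x[best_i, ]
    d2 <- best_d2
  }
  centers
}

#' Assign compartments to clusters by marker scoring
#'
#' For every cluster, the marker score of a compartment is the mean (over
#' that compartment's panel genes) of the cluster-mean z-scored normalized
#' expression. The argmax compartment is assigned when its score beats the
#' runner-up by `assignment_margin`; otherwise the cluster is
#' `"unassigned"`. Tumor and normal-epithelial calls additionally require
#' the cluster's majority tissue to agree (tumor clusters majority-tumor,
#' epithelial majority-normal). Cells in T-cell clusters are split into
#' `T_tumor` / `T_normal` by their own tissue label.
#'
#' @param cells a [cell_matrix()] whose metadata carries `tissue`.
#' @param normalized genes x cells normalized matrix.
#' @param clusters named integer vector from [cluster_cells()].
#' @param panel a [marker_panel()].
#' @param cfg an [annotation_config()].
#' @return List with `cell_types` (tibble: cell_id, cluster, cell_type) and
#'   `cluster_scores` (tibble: cluster, compartment, score, assigned).
#' @export
assign_cell_types <- function(cells, normalized, clusters,
                              panel = marker_panel(),
                              cfg = annotation_config()) {
  present <- lapply(panel, intersect, rownames(normalized))
  if (all(lengths(present) == 0)) stop_input("no marker genes present in matrix")
  for (nm in names(panel)) {
    missing <- setdiff(panel[[nm]], rownames(normalized))
    if (length(missing)) {
      rlang::warn(sprintf("marker gene(s) absent for %s: %s", nm,
                          paste(missing, collapse = ", ")))
    }
    if (length(present[[nm]]) == 0) {
      stop_input(sprintf("all marker genes absent for compartment %s", nm))
    }
  }
  marker_genes <- unlist(present)
  clusters <- clusters[colnames(normalized)]
  k <- sort(unique(clusters))
  # cluster-mean expression of each marker gene, z-scored across clusters
  cl_mean <- sapply(k, function(cl) {
    Matrix::rowSums(normalized[marker_genes, clusters == cl, drop = FALSE]) /
      sum(clusters == cl)
  })
  cl_mean <- matrix(cl_mean, nrow = length(marker_genes),
                    dimnames = list(marker_genes, k))
  zz <- t(scale(t(cl_mean)))
  zz[is.na(zz)] <- 0
  scores <- sapply(names(present), function(nm) {
    colMeans(zz[present[[nm]], , drop = FALSE])
  })
  scores <- matrix(scores, nrow = length(k),
                   dimnames = list(k, names(present)))

  tissue <- cells$cell_meta$tissue[match(colnames(normalized),
                                         cells$cell_meta$cell_id)]
  maj_tumor <- vapply(k, function(cl) {
    mean(tissue[clusters == cl] == "tumor") > 0.5
  }, logical(1))

  assigned <- character(length(k))
  for (i in seq_along(k)) {
    s <- sort(scores[i, ], decreasing = TRUE)
    top <- names(s)[1]
    gap <- s[1] - ifelse(length(s) > 1, s[2], -Inf)
    # a compartment call requires the cluster to overexpress the markers
    # (positive z), not merely to be the least-depleted candidate
    if (gap < cfg$assignment_margin || s[1] <= 0) {
      assigned[i] <- "unassigned"
    } else if (top == "tumor") {
      assigned[i] <- if (maj_tumor[i]) "tumor_epithelial" else "unassigned"
    } else if (top == "epithelial") {
      assigned[i] <- if (!maj_tumor[i]) "normal_epithelial" else "unassigned"
    } else if (top == "T") {
      assigned[i] <- "T"
    } else {
      assigned[i] <- "unassigned"
    }
  }
  names(assigned) <- k

  cell_type <- assigned[as.character(clusters)]
  is_t <- cell_type == "T"
  cell_type[is_t & tissue == "tumor"] <- "T_tumor"
  cell_type[is_t & tissue == "normal"] <- "T_normal"

  list(
    cell_types = tibble(cell_id = colnames(normalized),
                        cluster = unname(clusters),
                        cell_type = unname(cell_type)),
    cluster_scores = tibble(cluster = rep(k, ncol(scores)),
                            compartment = rep(colnames(scores), each = length(k)),
                            score = as.vector(scores)) |>
      left_join(tibble(cluster = k, assigned = unname(assigned)), by = "cluster")
  )
}

#' Run QC and annotation end-to-end
#'
#' QC -> normalize -> HVG -> PCA -> k-means -> marker assignment, the fixed
#' pipeline order.
#'
#' @param cells raw [cell_matrix()].
#' @param qc a [qc_config()].
#' @param cfg an [annotation_config()].
#' @param panel a [marker_panel()].
#' @return List: `cells` (QC-passed, `cell_meta` gains cluster/cell_type),
#'   `normalized`, `hvg`, `pca`, `annotation` (the [assign_cell_types()]
#'   output), `qc_removed`.
#' @export
annotate_cells <- function(cells, qc = qc_config(), cfg = annotation_config(),
                           panel = marker_panel()) {
  kept <- qc_filter(cells, qc)
  normalized <- normalize_log(kept)
  hvg <- select_hvg(normalized, min(cfg$n_hvg, nrow(normalized)))
  pca <- pca_embed(normalized, hvg, cfg$n_pcs)
  clusters <- cluster_cells(pca$embedding, cfg$k_clusters, cfg$cluster_seed)
  ann <- assign_cell_types(kept, normalized, clusters, panel, cfg)
  kept$cell_meta <- kept$cell_meta |>
    left_join(ann$cell_types, by = "cell_id")
  list(cells = kept, normalized = normalized, hvg = hvg, pca = pca,
       annotation = ann, qc_removed = attr(kept, "qc_removed"))
}
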