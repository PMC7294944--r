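#' Volcano plot of a DE table
#'
#' @param object a `de_table` (direction-labeled via [call_direction()]).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.de_table <- function(object, ...) {
  df <- object
  if (is.null(df$direction)) df$direction <- "ns"
  ggplot(df, aes(x = .data$lfc, y = -log10(pmax(.data$p_value, 1e-300)),
                 colour = .data$direction)) +
    geom_point(size = 0.6, alpha = 0.6) +
    labs(x = "log2 fold change", y = "-log10 P", colour = NULL) +
    theme_minimal()
}

#' Feature-importance plot of a risk model
#'
#' @param object a `risk_model_report`.
#' @param top_n features to show (default 10).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.risk_model_report <- function(object, top_n = 10, ...) {
  df <- head(object$importances, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot(df, aes(x = .data$feature, y = .data$gain)) +
    geom_col() + coord_flip() +
    labs(x = NULL, y = "gain importance") +
    theme_minimal()
}

#' Kaplan-Meier step plot for a median-split gene
#'
#' @param gene gene symbol.
#' @param bulk a [bulk_cohort()].
#' @return A ggplot of the two product-limit curves.
#' @export
plot_km_gene <- function(gene, bulk) {
  gene <- toupper(gene)
  if (!gene %in% rownames(bulk$expr)) stop_input("gene absent from bulk")
  cl <- bulk$clinical
  sp <- median_split(stats::setNames(bulk$expr[gene, cl$sample], cl$sample))
  if (sp$unsplittable) stop_input("gene is unsplittable (constant expression)")
  mk <- function(ids, lab) {
    d <- cl[cl$sample %in% ids, ]
    km_curve(d$time, d$event) |> mutate(group = lab)
  }
  df <- bind_rows(mk(sp$high, "high"), mk(sp$low, "low"))
  ggplot(df, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step() +
    labs(x = "time (days)", y = "survival probability",
         colour = paste0(gene, " expression")) +
    theme_minimal()
}

#' PCA scatter of annotated cells
#'
#' @param annotated result of [annotate_cells()].
#' @param colour_by metadata column to colour by (default `"cell_type"`).
#' @return A ggplot of cells in PC1-2.
#' @export
plot_cell_pca <- function(annotated, colour_by = "cell_type") {
  emb <- annotated$pca$embedding
  meta <- annotated$cells$cell_meta
  df <- tibble(cell_id = rownames(emb), PC1 = emb[, 1], PC2 = emb[, 2]) |>
    left_join(meta, by = "cell_id")
  ggplot(df, aes(x = .data$PC1, y = .data$PC2,
                 colour = .data[[colour_by]])) +
    geom_point(size = 0.5, alpha = 0.6) +
    labs(colour = colour_by) +
    theme_minimal()
}
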