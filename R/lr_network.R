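#' Tie-corrected Spearman correlation with t-approximation P value
#'
#' Pearson correlation on mid-ranks (the tie-corrected Spearman
#' coefficient), with a two-sided P value from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom;
#' `|rho| = 1` gives `p = 0`.
#'
#' @param x,y numeric vectors of equal length (pairs with missing values
#'   removed first).
#' @return List with `rho` and `p_raw`; `rho` is `NA` (with `p_raw` `NA`)
#'   when either vector is constant.
#' @export
spearman <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n != length(y)) stop_input("x and y must have equal length")
  if (n < 3) stop_input("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p_raw = NA_real_, n = n))
  }
  rx <- rank(x); ry <- rank(y)   # mid-ranks for ties
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_raw = p, n = n)
}

#' Multiple-testing adjustment (Benjamini-Hochberg or Holm)
#'
#' BH step-up: `p_adj(i) = min over j >= i of m * p(j) / j` over the order
#' statistics; Holm step-down: running maximum of `(m - i + 1) * p(i)`.
#' Adjusted values are clipped to [0, 1].
#'
#' @param p numeric vector of P values in [0, 1].
#' @param method `"BH"` (default) or `"holm"`.
#' @return Numeric vector of adjusted P values, in input order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "holm")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_input("p values must lie in [0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  if (method == "BH") {
    adj <- rev(cummin(rev(m * ps / seq_len(m))))
  } else {
    adj <- cummax((m - seq_len(m) + 1) * ps)
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Co-expression validation configuration
#'
#' @param rho_min minimum Spearman coefficient (exclusive) for a pair to
#'   pass (default 0.4).
#' @param alpha_adj adjusted-P threshold (default 0.05).
#' @param adjust_method `"BH"` (default) or `"holm"`.
#' @param min_bulk_samples minimum cohort size for the Spearman stage.
#' @return A list of class `coexpr_config`.
#' @export
coexpr_config <- function(rho_min = 0.4, alpha_adj = 0.05,
                          adjust_method = c("BH", "holm"),
                          min_bulk_samples = 20L) {
  structure(list(rho_min = assert_fraction(rho_min, "rho_min", 1e-9, 1 - 1e-9),
                 alpha_adj = assert_fraction(alpha_adj, "alpha_adj", 1e-9, 1 - 1e-9),
                 adjust_method = match.arg(adjust_method),
                 min_bulk_samples = assert_count(min_bulk_samples,
                                                 "min_bulk_samples", 3L)),
            class = "coexpr_config")
}

#' Intracellular concordant LR pairs
#'
#' Selects catalog pairs whose ligand and receptor are both labeled `up`
#' (up list) or both `down` (down list) in one compartment's
#' tumor-vs-normal DE table. Pairs with either gene absent from the table
#' are skipped and counted.
#'
#' @param de a direction-labeled DE table from [call_direction()].
#' @param catalog an [lr_catalog()].
#' @return List with `up` and `down` pair tibbles (ligand, receptor,
#'   ligand_p, receptor_p, ligand_lfc, receptor_lfc) and `n_skipped`.
#' @export
match_intracellular_pairs <- function(de, catalog) {
  ann <- annotate_pairs(catalog, de, de)
  present <- ann$present
  list(
    up = present |> filter(.data$ligand_dir == "up" & .data$receptor_dir == "up") |>
      select(-"ligand_dir", -"receptor_dir"),
    down = present |> filter(.data$ligand_dir == "down" & .data$receptor_dir == "down") |>
      select(-"ligand_dir", -"receptor_dir"),
    n_skipped = ann$n_skipped
  )
}

#' Directional crosstalk LR pairs
#'
#' A pair is included when the ligand is labeled `up` in the source
#' compartment's DE table and the receptor `up` in the target
#' compartment's, defining a signaling direction (tumor cells to T cells or
#' the reverse).
#'
#' @param de_source,de_target direction-labeled DE tables for the ligand's
#'   and the receptor's compartments (must be distinct tables).
#' @param catalog an [lr_catalog()].
#' @param direction label recorded on the result, e.g. `"tumor_to_T"`.
#' @return List with `pairs` tibble and `n_skipped`.
#' @export
match_crosstalk_pairs <- function(de_source, de_target, catalog,
                                  direction = "tumor_to_T") {
  if (identical(de_source$gene, de_target$gene) &&
      identical(de_source$p_value, de_target$p_value) &&
      identical(de_source$lfc, de_target$lfc)) {
    stop_input("source and target DE tables are identical; crosstalk needs two compartments")
  }
  ann <- annotate_pairs(catalog, de_source, de_target)
  list(
    pairs = ann$present |>
      filter(.data$ligand_dir == "up" & .data$receptor_dir == "up") |>
      select(-"ligand_dir", -"receptor_dir") |>
      mutate(category = direction),
    n_skipped = ann$n_skipped
  )
}

# join a catalog against the ligand-side and receptor-side DE tables
annotate_pairs <- function(catalog, de_ligand, de_receptor) {
  lg <- de_ligand |>
    select(ligand = "gene", ligand_p = "p_used", ligand_lfc = "lfc",
           ligand_dir = "direction")
  rc <- de_receptor |>
    select(receptor = "gene", receptor_p = "p_used", receptor_lfc = "lfc",
           receptor_dir = "direction")
  joined <- as_tibble(catalog) |>
    left_join(lg, by = "ligand") |>
    left_join(rc, by = "receptor")
  absent <- is.na(joined$ligand_dir) | is.na(joined$receptor_dir)
  list(present = joined[!absent, ], n_skipped = sum(absent))
}

#' Validate LR pairs by bulk co-expression
#'
#' Computes the tie-corrected Spearman correlation of each pair's ligand
#' and receptor across bulk samples, adjusts P values within the supplied
#' pair family, and flags pairs passing `rho > rho_min` AND
#' `p_adj < alpha_adj`. Pairs with either gene absent from the bulk matrix
#' are dropped and counted; pairs with constant expression are flagged and
#' excluded from the pass set.
#'
#' @param pairs tibble with ligand/receptor columns (plus any provenance
#'   columns, preserved).
#' @param bulk a [bulk_cohort()].
#' @param cfg a [coexpr_config()].
#' @return List with `calls` (the pairs plus rho, rho_p_raw, rho_p_adj,
#'   passed_coexpr) and `n_absent`.
#' @export
validate_coexpression <- function(pairs, bulk, cfg = coexpr_config()) {
  if (ncol(bulk$expr) < cfg$min_bulk_samples) {
    stop_input(sprintf("bulk cohort has %d samples; need at least %d",
                       ncol(bulk$expr), cfg$min_bulk_samples))
  }
  pairs <- as_tibble(pairs)
  present <- pairs$ligand %in% rownames(bulk$expr) &
    pairs$receptor %in% rownames(bulk$expr)
  kept <- pairs[present, ]
  if (nrow(kept) == 0) {
    return(list(calls = kept |> mutate(rho = numeric(0), rho_p_raw = numeric(0),
                                       rho_p_adj = numeric(0),
                                       passed_coexpr = logical(0)),
                n_absent = sum(!present)))
  }
  res <- purrr::map2(kept$ligand, kept$receptor, function(l, r) {
    spearman(bulk$expr[l, ], bulk$expr[r, ])
  })
  rho <- purrr::map_dbl(res, "rho")
  p_raw <- purrr::map_dbl(res, "p_raw")
  ok <- !is.na(p_raw)
  p_adj <- rep(NA_real_, length(p_raw))
  if (any(ok)) p_adj[ok] <- adjust_pvalues(p_raw[ok], cfg$adjust_method)
  calls <- kept |>
    mutate(rho = rho, rho_p_raw = p_raw, rho_p_adj = p_adj,
           passed_coexpr = !is.na(rho) & rho > cfg$rho_min &
             !is.na(p_adj) & p_adj < cfg$alpha_adj)
  list(calls = calls, n_absent = sum(!present))
}
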