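#' Two-part hurdle differential-expression test
#'
#' For each gene, compares two cell groups with the two-part test underlying
#' MAST-style single-cell DE: (i) a detection component — a likelihood-ratio
#' (G) test of equal Bernoulli detection probability on the 2x2
#' detected-by-group table (1 df); and (ii) a continuous component — a
#' Welch-style Gaussian test on the log-normalized values among detected
#' cells (squared Welch t, 1 df), skipped with statistic 0 when either group
#' has fewer than two detected cells. The combined statistic is the sum,
#' with a chi-squared reference whose degrees of freedom equal the number of
#' contributing components. Genes detected in neither group are dropped.
#'
#' The log2 fold change is computed on group means of the 10k-scaled
#' (de-logged) expression with pseudocount 1.
#'
#' @param normalized genes x cells matrix from [normalize_log()].
#' @param cells_a,cells_b disjoint, non-empty character vectors of cell ids
#'   (group A is the "condition", e.g. tumor; positive lfc means higher
#'   in A).
#' @return A `de_table` tibble: gene, lfc, rate_a, rate_b, stat, df,
#'   p_value.
#' @export
hurdle_test <- function(normalized, cells_a, cells_b) {
  if (length(cells_a) == 0 || length(cells_b) == 0) {
    stop_input("both cell groups must be non-empty")
  }
  if (length(intersect(cells_a, cells_b))) {
    stop_input("cell groups must be disjoint")
  }
  miss <- setdiff(c(cells_a, cells_b), colnames(normalized))
  if (length(miss)) {
    stop_input(sprintf("%d cell id(s) absent from the matrix", length(miss)))
  }
  a <- normalized[, cells_a, drop = FALSE]
  b <- normalized[, cells_b, drop = FALSE]
  na <- length(cells_a); nb <- length(cells_b)

  det_a <- Matrix::rowSums(a > 0)
  det_b <- Matrix::rowSums(b > 0)
  keep <- (det_a + det_b) > 0
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  det_a <- det_a[keep]; det_b <- det_b[keep]

  g_stat <- g_test_2x2(det_a, na - det_a, det_b, nb - det_b)

  # continuous component over detected cells, via sparse row sums
  s1a <- Matrix::rowSums(a); s2a <- row_sumsq(a)
  s1b <- Matrix::rowSums(b); s2b <- row_sumsq(b)
  mean_a <- ifelse(det_a > 0, s1a / det_a, 0)
  mean_b <- ifelse(det_b > 0, s1b / det_b, 0)
  var_a <- ifelse(det_a > 1, pmax((s2a - det_a * mean_a^2) / (det_a - 1), 0), NA)
  var_b <- ifelse(det_b > 1, pmax((s2b - det_b * mean_b^2) / (det_b - 1), 0), NA)
  can_cont <- det_a >= 2 & det_b >= 2
  se2 <- var_a / det_a + var_b / det_b
  t_stat <- ifelse(can_cont & se2 > 0, (mean_a - mean_b) / sqrt(se2), 0)
  cont_stat <- ifelse(can_cont, t_stat^2, 0)

  stat <- g_stat + cont_stat
  df <- 1L + as.integer(can_cont)
  p <- pchisq(stat, df = df, lower.tail = FALSE)

  # fold change on the de-logged 10k scale, pseudocount 1
  ea <- a; ea@x <- expm1(ea@x)
  eb <- b; eb@x <- expm1(eb@x)
  lfc <- log2((Matrix::rowSums(ea) / na + 1) / (Matrix::rowSums(eb) / nb + 1))

  structure(
    tibble(gene = rownames(a), lfc = lfc,
           rate_a = det_a / na, rate_b = det_b / nb,
           stat = stat, df = df, p_value = p),
    class = c("de_table", class(tibble())))
}

row_sumsq <- function(m) {
  m@x <- m@x^2
  Matrix::rowSums(m)
}

# vectorized 2x2 likelihood-ratio (G) statistic for equal detection
# probability; 0*log(0) taken as 0
g_test_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  # G = 2 * [ sum O log O - sum(row) log(row) - sum(col) log(col) + n log n ]
  2 * (xlogx(a) + xlogx(b) + xlogx(c) + xlogx(d) -
         xlogx(a + b) - xlogx(c + d) - xlogx(a + c) - xlogx(b + d) +
         xlogx(n))
}

#' Call DE direction at a significance threshold
#'
#' Labels each gene `up` (p < alpha and lfc > 0), `down` (p < alpha and
#' lfc < 0), or `ns`. Raw P values are used by default, mirroring the
#' single-cell DE convention of thresholding the unadjusted hurdle P at
#' 0.05; `adjust = "BH"` applies Benjamini-Hochberg first.
#'
#' @param de a `de_table` from [hurdle_test()].
#' @param alpha significance threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return The table with columns `p_used` and `direction` added.
#' @export
call_direction <- function(de, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p_used <- if (adjust == "BH") adjust_pvalues(de$p_value, "BH") else de$p_value
  de |>
    mutate(p_used = p_used,
           direction = dplyr::case_when(
             p_used < alpha & .data$lfc > 0 ~ "up",
             p_used < alpha & .data$lfc < 0 ~ "down",
             TRUE ~ "ns"))
}
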