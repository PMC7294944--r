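#' Median split of expression values
#'
#' Splits samples into a high group (strictly greater than the cohort
#' median) and a low group (less than or equal to the median — ties at the
#' median go low). The median is the midpoint of the two central order
#' statistics for even n.
#'
#' @param expr named numeric vector of per-sample expression.
#' @return List with `high` and `low` (character ids), `median`, and
#'   `unsplittable` (TRUE when all values are equal, in which case `high`
#'   is empty).
#' @export
median_split <- function(expr) {
  if (length(expr) < 2) stop_input("median_split needs at least 2 samples")
  if (is.null(names(expr))) names(expr) <- as.character(seq_along(expr))
  expr <- expr[is.finite(expr)]
  med <- median(expr)
  high <- names(expr)[expr > med]
  low <- names(expr)[expr <= med]
  list(high = high, low = low, median = med,
       unsplittable = length(high) == 0)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator of the survival function (via
#' [survival::survfit()]), with S(0) = 1 prepended.
#'
#' @param times positive survival/censoring times.
#' @param events 0/1 event indicators.
#' @return A tibble: time, n_risk, n_event, surv (non-increasing step
#'   function).
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0) stop_input("km_curve needs at least one subject")
  if (any(times <= 0)) stop_input("times must be positive")
  if (!all(events %in% c(0, 1))) stop_input("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  tibble(time = c(0, fit$time),
         n_risk = c(length(times), fit$n.risk),
         n_event = c(0, fit$n.event),
         surv = c(1, fit$surv))
}

#' Log-rank test for two survival curves
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' summed over distinct event times (via [survival::survdiff()]), referred
#' to chi-squared on 1 df.
#'
#' @param times_a,events_a,times_b,events_b per-group times and indicators.
#' @return List with `chi_square`, `p_value`, `n_a`, `n_b`; both are `NA`
#'   with `undefined = TRUE` when neither group has an event.
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    stop_input("both groups must be non-empty")
  }
  if (sum(events_a) + sum(events_b) == 0) {
    return(list(chi_square = NA_real_, p_value = NA_real_,
                n_a = length(times_a), n_b = length(times_b),
                undefined = TRUE))
  }
  grp <- factor(rep(c("A", "B"), c(length(times_a), length(times_b))))
  sv <- survival::Surv(c(times_a, times_b), c(events_a, events_b))
  fit <- survival::survdiff(sv ~ grp)
  list(chi_square = fit$chisq,
       p_value = pchisq(fit$chisq, df = 1, lower.tail = FALSE),
       n_a = length(times_a), n_b = length(times_b), undefined = FALSE)
}

#' Median-split survival screen over genes
#'
#' For each gene, splits the cohort at the median expression and compares
#' high vs low survival with the log-rank test. Significance is flagged at
#' raw P < alpha (no correction, the screening convention here); BH-adjusted
#' P values are reported alongside. Unsplittable genes (constant
#' expression) are reported separately.
#'
#' @param genes gene symbols to screen (absent genes are skipped and
#'   listed).
#' @param bulk a [bulk_cohort()].
#' @param alpha raw significance threshold (default 0.05).
#' @return A `survival_screen` list: `results` tibble (gene, n_high, n_low,
#'   chi_square, p_value, p_bh, direction, significant), `unsplittable`,
#'   `skipped`.
#' @export
survival_screen <- function(genes, bulk, alpha = 0.05) {
  genes <- toupper(genes)
  skipped <- setdiff(genes, rownames(bulk$expr))
  genes <- intersect(genes, rownames(bulk$expr))
  cl <- bulk$clinical
  rows <- list()
  unsplittable <- character(0)
  for (g in genes) {
    ex <- stats::setNames(bulk$expr[g, cl$sample], cl$sample)
    sp <- median_split(ex)
    if (sp$unsplittable) {
      unsplittable <- c(unsplittable, g)
      next
    }
    hi <- cl[cl$sample %in% sp$high, ]
    lo <- cl[cl$sample %in% sp$low, ]
    lr <- logrank(hi$time, hi$event, lo$time, lo$event)
    dir_val <- median_surv_diff(hi, lo)
    rows[[g]] <- tibble(gene = g, n_high = nrow(hi), n_low = nrow(lo),
                        chi_square = lr$chi_square, p_value = lr$p_value,
                        direction = dir_val)
  }
  results <- if (length(rows)) bind_rows(rows) else {
    tibble(gene = character(), n_high = integer(), n_low = integer(),
           chi_square = numeric(), p_value = numeric(), direction = numeric())
  }
  if (nrow(results)) {
    okp <- !is.na(results$p_value)
    results$p_bh <- NA_real_
    results$p_bh[okp] <- adjust_pvalues(results$p_value[okp], "BH")
    results$significant <- !is.na(results$p_value) & results$p_value < alpha
  } else {
    results$p_bh <- numeric(0)
    results$significant <- logical(0)
  }
  structure(list(results = results, unsplittable = unsplittable,
                 skipped = skipped, alpha = alpha),
            class = "survival_screen")
}

# sign of (median survival high - low); NA when either median undefined
median_surv_diff <- function(hi, lo) {
  med <- function(d) {
    fit <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
    unname(summary(fit)$table["median"])
  }
  mh <- med(hi); ml <- med(lo)
  if (is.na(mh) || is.na(ml)) return(NA_real_)
  sign(mh - ml)
}

#' @export
print.survival_screen <- function(x, ...) {
  cat(sprintf("<survival_screen> %d genes tested, %d significant at P < %g\n",
              nrow(x$results), sum(x$results$significant), x$alpha))
  if (length(x$unsplittable)) {
    cat("  unsplittable:", paste(x$unsplittable, collapse = ", "), "\n")
  }
  if (length(x$skipped)) {
    cat("  absent from bulk:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.survival_screen <- function(x, ...) x$results

#' @export
glance.survival_screen <- function(x, ...) {
  tibble(n_tested = nrow(x$results),
         n_significant = sum(x$results$significant),
         n_unsplittable = length(x$unsplittable),
         n_skipped = length(x$skipped),
         alpha = x$alpha)
}
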