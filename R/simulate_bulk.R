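#' Simulate a bulk tumor cohort with planted co-expression, survival and stage
#'
#' Emulates a TCGA-LUAD-style validation cohort on a log2(x+1) continuous
#' scale. For every planted LR pair, ligand and receptor share a per-sample
#' latent factor weighted so the expected Spearman correlation equals
#' `bulk_rho_target` (via the bivariate-normal relation
#' `rho_pearson = 2 sin(pi rho_spearman / 6)`); decoy-pair genes are
#' independent. Survival times are exponential with hazard
#' `h0 * exp(sum(beta_g * z_g))` over the prognostic genes' expression
#' z-scores, with independent uniform censoring calibrated to
#' `censor_rate_target`. The AJCC stage label (IA vs IB-IV) is drawn from a
#' logistic model on the same risk score, so the stage classifier has
#' recoverable signal.
#'
#' @param config a [sim_config()].
#' @param truth the `truth_manifest` produced by [simulate_sc()] under the
#'   same config.
#' @return A `bulk_cohort`: list with `expr` (genes x samples numeric matrix,
#'   log scale) and `clinical` (tibble: sample, time, event, stage).
#' @export
simulate_bulk_clinical <- function(config, truth) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (!inherits(truth, "truth_manifest")) {
    stop_input("`truth` must be a truth_manifest from simulate_sc()")
  }
  if (!identical(truth$config$seed, config$seed)) {
    stop_input("`truth` was generated under a different config/seed")
  }
  with_seed(child_seed(config$seed, 2L), simulate_bulk_impl(config, truth))
}

simulate_bulk_impl <- function(cfg, truth) {
  genes <- truth$genes
  n_s <- cfg$bulk_n_samples
  sample_ids <- sprintf("S%03d", seq_len(n_s))

  gene_mean <- rnorm(length(genes), mean = 6, sd = 1.5)
  gene_sd <- rep(1, length(genes))
  z <- matrix(rnorm(length(genes) * n_s), nrow = length(genes),
              dimnames = list(genes, sample_ids))

  # plant co-expression: replace both genes' standardized values with a
  # shared latent factor mixture achieving the Pearson rho that maps to
  # the requested Spearman rho under bivariate normality
  rho_p <- 2 * sin(pi * cfg$bulk_rho_target / 6)
  w <- sqrt(abs(rho_p)) * sign(rho_p)
  planted <- truth$pairs |> filter(.data$category != "decoy")
  for (i in seq_len(nrow(planted))) {
    lat <- rnorm(n_s)
    z[planted$ligand[i], ] <- w * lat +
      sqrt(1 - w^2) * rnorm(n_s)
    z[planted$receptor[i], ] <- w * lat +
      sqrt(1 - w^2) * rnorm(n_s)
  }
  expr <- gene_mean + gene_sd * z
  dimnames(expr) <- list(genes, sample_ids)

  # risk score over prognostic genes (z-scored expression, signed betas)
  score <- rep(0, n_s)
  if (nrow(truth$prognostic)) {
    for (i in seq_len(nrow(truth$prognostic))) {
      g <- truth$prognostic$gene[i]
      zg <- (expr[g, ] - mean(expr[g, ])) / sd(expr[g, ])
      score <- score + truth$prognostic$sign[i] * cfg$prognostic_beta * zg
    }
  }

  h0 <- log(2) / 1000   # baseline median survival ~1000 days
  rate <- h0 * exp(score)
  t_event <- rexp(n_s, rate = rate)
  # uniform censoring U(0, cmax); cmax solves E[P(censored)] = target
  cens_frac <- function(cmax) mean((1 - exp(-rate * cmax)) / (rate * cmax))
  cmax <- uniroot(function(cc) cens_frac(cc) - cfg$censor_rate_target,
                  lower = 1e-3, upper = 1e7)$root
  t_cens <- runif(n_s, 0, cmax)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  time <- pmax(time, 1 / 24)  # keep times strictly positive (fraction of a day)

  # stage: logistic on the shared risk score; intercept calibrated so the
  # expected high-risk (IB-IV) prevalence matches the LUAD cohort regime
  slope <- 1.2
  target_high <- 333 / 460
  a <- uniroot(function(aa) mean(plogis(aa + slope * score)) - target_high,
               lower = -20, upper = 20)$root
  high <- rbinom(n_s, 1, plogis(a + slope * score)) == 1
  stage <- ifelse(high,
                  sample(c("IB", "IIA", "IIB", "IIIA", "IIIB", "IV"),
                         n_s, replace = TRUE),
                  "IA")

  bulk_cohort(expr,
              tibble(sample = sample_ids, time = time, event = event,
                     stage = stage))
}

#' Bulk cohort container
#'
#' Genes-by-samples expression on a continuous log scale plus a clinical
#' table (sample, survival time in days, event indicator, AJCC stage).
#'
#' @param expr numeric matrix, genes x samples, with dimnames.
#' @param clinical data frame with columns sample, time, event, stage.
#' @return A `bulk_cohort` object.
#' @export
bulk_cohort <- function(expr, clinical) {
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop_input("`expr` must have gene rownames and sample colnames")
  }
  rownames(expr) <- toupper(rownames(expr))
  if (anyDuplicated(rownames(expr))) stop_input("duplicate gene symbols in bulk expr")
  clinical <- as_tibble(clinical)
  need <- c("sample", "time", "event", "stage")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) {
    stop_format(paste0("clinical table missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  if (!is.numeric(clinical$time)) stop_format("clinical `time` must be numeric")
  bad <- which(!is.finite(clinical$time) | clinical$time <= 0)
  if (length(bad)) {
    stop_format(sprintf("clinical row %d: time must be positive", bad[1]))
  }
  if (!all(clinical$event %in% c(0, 1))) {
    stop_format("clinical `event` must be 0/1")
  }
  absent <- setdiff(clinical$sample, colnames(expr))
  if (length(absent)) {
    stop_format(paste0("clinical sample(s) absent from expression: ",
                       paste(head(absent, 5), collapse = ", ")))
  }
  structure(list(expr = expr, clinical = clinical), class = "bulk_cohort")
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat(sprintf("<bulk_cohort> %d genes x %d samples; %d clinical rows (%.0f%% events)\n",
              nrow(x$expr), ncol(x$expr), nrow(x$clinical),
              100 * mean(x$clinical$event)))
  invisible(x)
}
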