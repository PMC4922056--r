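#' Prepare lipid phenotypes for association analysis
#'
#' Log-transforms TG, derives LDL-C by the Friedewald formula
#' (LDL = TC - HDL - TG/2.2, mmol/L) where absent, and scales each lipid to
#' mean 0, SD 1 (within the supplied table, i.e. per cohort when called per
#' cohort).
#'
#' @param phenotypes data.frame with columns `TG`, `HDL` and `TC` (and
#'   optionally `LDL`).
#' @return data.frame with standardized columns `TG`, `LDL`, `HDL`.
#' @export
prepare_lipids <- function(phenotypes) {
  if (any(phenotypes$TG <= 0))
    stop("non-positive TG values at samples: ",
         paste(utils::head(which(phenotypes$TG <= 0), 10), collapse = ", "))
  ldl <- if ("LDL" %in% names(phenotypes)) phenotypes$LDL
         else phenotypes$TC - phenotypes$HDL - phenotypes$TG / 2.2
  out <- data.frame(TG = log(phenotypes$TG), LDL = ldl, HDL = phenotypes$HDL)
  for (j in names(out)) {
    s <- stats::sd(out[[j]])
    if (!is.finite(s) || s == 0)
      stop("cannot scale constant lipid column: ", j)
    out[[j]] <- as.vector(scale(out[[j]]))
  }
  out
}

# The standard covariate set: gender, age, cell percentages, bisulfite
# plate and array position (categoricals as factors).
ewas_covariates <- function(phenotypes, extra = NULL) {
  cols <- c("gender", "age", "mono_pct", "lymph_pct", "neut_pct",
            "bisplate", "position")
  missing_cols <- setdiff(cols, names(phenotypes))
  if (length(missing_cols) > 0)
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "))
  out <- phenotypes[, cols]
  if (!is.null(extra)) {
    missing_extra <- setdiff(extra, names(phenotypes))
    if (length(missing_extra) > 0)
      stop("missing covariate column(s): ", paste(missing_extra, collapse = ", "))
    out <- cbind(out, phenotypes[, extra, drop = FALSE])
  }
  out
}

#' Per-cohort epigenome-wide association scan of one lipid
#'
#' Fits the covariate-adjusted linear model of every CpG on the prepared
#' (log-transformed, standardized) lipid, then applies genomic control to
#' the t-statistics: nominal p-values and standard errors are recomputed
#' from the corrected statistics. Zero-variance CpGs are flagged and
#' excluded from the genomic-control median.
#'
#' @param cohort A cohort list (`methylation`, `phenotypes`).
#' @param lipid One of "TG", "LDL", "HDL".
#' @param extra_covariates Optional extra phenotype columns to adjust for.
#' @param apply_gc Apply genomic control (default TRUE).
#' @return data.frame (cpg, mean_beta, estimate, se, statistic, p, n, df)
#'   with attribute `lambda`; flagged CpGs carry NA statistics.
#' @export
run_ewas_cohort <- function(cohort, lipid = c("TG", "LDL", "HDL"),
                            extra_covariates = NULL, apply_gc = TRUE) {
  lipid <- match.arg(lipid)
  ph <- cohort$phenotypes
  if (nrow(ph) < 50) warning("fewer than 50 samples in cohort")
  x <- prepare_lipids(ph)[[lipid]]
  Y <- cohort$methylation
  ok <- apply(Y, 2, stats::sd) > 1e-10
  res <- fast_assoc(Y[, ok, drop = FALSE], x,
                    covariates = ewas_covariates(ph, extra_covariates))
  lambda <- NA_real_
  if (apply_gc) {
    gc <- suppressWarnings(genomic_control(res$statistic))
    lambda <- gc$lambda
    res$statistic <- gc$corrected
    res$se <- abs(res$estimate / res$statistic)
    res$p <- 2 * stats::pt(-abs(res$statistic), res$df)
  }
  out <- data.frame(cpg = colnames(Y), mean_beta = colMeans(Y),
                    estimate = NA_real_, se = NA_real_, statistic = NA_real_,
                    p = NA_real_, n = nrow(Y), df = NA_real_,
                    flagged = !ok, row.names = NULL)
  out[ok, c("estimate", "se", "statistic", "p", "df")] <-
    res[, c("estimate", "se", "statistic", "p", "df")]
  attr(out, "lambda") <- lambda
  out
}

#' Fixed-effect meta-analysis of per-cohort EWAS tables
#'
#' Pools per-CpG estimates by inverse variance, applies genomic control to
#' the resulting z-statistics, recomputes p-values (and standard errors)
#' from the corrected z, and adjusts for multiple testing by
#' Benjamini-Hochberg. Reports the per-CpG cross-cohort sign-consistency
#' count, the pooled mean methylation and the percent-per-SD estimate.
#'
#' @param cohort_tables List of tables from [run_ewas_cohort] (CpG sets are
#'   intersected with a warning if they differ).
#' @param cpg_meta Optional CpG annotation (`cpg`, `chrom`, `pos`) to merge.
#' @param q_threshold Significance threshold on the FDR-adjusted p.
#' @return data.frame of class `ewas_table` with per-CpG pooled results;
#'   attributes `lambda_meta` and `lambda_cohorts`.
#' @export
meta_ewas <- function(cohort_tables, cpg_meta = NULL, q_threshold = 0.05) {
  k <- length(cohort_tables)
  if (k == 0) stop("no cohort tables supplied")
  if (k == 1) message("single cohort: meta-analysis is a pass-through")
  sets <- lapply(cohort_tables, function(t) t$cpg[!t$flagged & is.finite(t$se)])
  common <- Reduce(intersect, sets)
  if (!all(lengths(sets) == length(common)))
    warning("CpG sets differ across cohorts; intersecting")
  est <- vapply(cohort_tables,
                function(t) t$estimate[match(common, t$cpg)], numeric(length(common)))
  se <- vapply(cohort_tables,
               function(t) t$se[match(common, t$cpg)], numeric(length(common)))
  mb <- vapply(cohort_tables,
               function(t) t$mean_beta[match(common, t$cpg)], numeric(length(common)))
  ns <- vapply(cohort_tables, function(t) t$n[1], numeric(1))
  est <- matrix(est, ncol = k); se <- matrix(se, ncol = k); mb <- matrix(mb, ncol = k)
  w <- 1 / se^2
  pooled <- rowSums(w * est) / rowSums(w)
  pooled_se <- 1 / sqrt(rowSums(w))
  z <- pooled / pooled_se
  gc <- suppressWarnings(genomic_control(z))
  z_corr <- gc$corrected
  se_corr <- abs(pooled / z_corr)
  p <- 2 * stats::pnorm(-abs(z_corr))
  q <- bh_fdr(p)
  sign_cons <- apply(sign(est) == sign(pooled), 1, sum)
  out <- data.frame(cpg = common,
                    mean_dnam_pct = 100 * as.vector(mb %*% ns / sum(ns)),
                    estimate = pooled,
                    estimate_pct_per_sd = 100 * pooled,
                    se = se_corr, z = z_corr, p = p, q = q,
                    n_cohorts = k, sign_consistency = sign_cons,
                    significant = q < q_threshold, row.names = NULL)
  if (!is.null(cpg_meta))
    out <- merge(cpg_meta, out, by = "cpg", sort = FALSE)
  attr(out, "lambda_meta") <- gc$lambda
  attr(out, "lambda_cohorts") <- vapply(cohort_tables,
                                        function(t) attr(t, "lambda") %||% NA_real_,
                                        numeric(1))
  class(out) <- c("ewas_table", "data.frame")
  out
}

#' Full EWAS of one lipid across all cohorts
#'
#' Convenience driver: per-cohort scan ([run_ewas_cohort]) followed by
#' [meta_ewas].
#'
#' @param study A `lipid_study`.
#' @param lipid One of "TG", "LDL", "HDL".
#' @param sample_filter Optional function(phenotypes) returning a logical
#'   keep-vector, applied per cohort.
#' @param extra_covariates Optional extra covariate column names.
#' @return An `ewas_table`.
#' @export
run_ewas <- function(study, lipid, sample_filter = NULL, extra_covariates = NULL) {
  tables <- lapply(study$cohorts, function(co) {
    if (!is.null(sample_filter)) {
      keep <- sample_filter(co$phenotypes)
      co$methylation <- co$methylation[keep, , drop = FALSE]
      co$phenotypes <- co$phenotypes[keep, , drop = FALSE]
    }
    run_ewas_cohort(co, lipid, extra_covariates = extra_covariates)
  })
  meta_ewas(tables, cpg_meta = study$cpg_meta)
}

#' Sensitivity re-runs of the EWAS
#'
#' Repeats the EWAS under sample restrictions (`fasted_only`,
#' `measured_cells_only`) or with added covariates (`+smoking`,
#' `+lipid_meds`, `+BMI`) and compares estimates to the baseline table.
#'
#' @param study A `lipid_study`.
#' @param lipid One of "TG", "LDL", "HDL".
#' @param options Character vector of options (see above).
#' @param baseline Optional precomputed baseline `ewas_table`.
#' @return Named list per option: `table` (the re-run `ewas_table`) and
#'   `delta` (data.frame cpg, baseline, sensitivity, delta).
#' @export
sensitivity_ewas <- function(study, lipid,
                             options = c("fasted_only", "measured_cells_only",
                                         "+smoking", "+lipid_meds", "+BMI"),
                             baseline = NULL) {
  options <- match.arg(options, several.ok = TRUE)
  if (is.null(baseline)) baseline <- run_ewas(study, lipid)
  out <- list()
  for (opt in options) {
    tab <- switch(
      opt,
      fasted_only = run_ewas(study, lipid,
                             sample_filter = function(ph) {
                               if (!"fasting" %in% names(ph))
                                 stop("configuration error: no fasting column")
                               ph$fasting == 1
                             }),
      measured_cells_only = run_ewas(study, lipid,
                                     sample_filter = function(ph) {
                                       if (!"cells_imputed" %in% names(ph))
                                         stop("configuration error: no cells_imputed column")
                                       ph$cells_imputed == 0
                                     }),
      `+smoking` = run_ewas(study, lipid, extra_covariates = "smoking"),
      `+lipid_meds` = run_ewas(study, lipid, extra_covariates = "lipid_meds"),
      `+BMI` = run_ewas(study, lipid, extra_covariates = "BMI")
    )
    m <- match(baseline$cpg, tab$cpg)
    out[[opt]] <- list(
      table = tab,
      delta = data.frame(cpg = baseline$cpg,
                         baseline = baseline$estimate,
                         sensitivity = tab$estimate[m],
                         delta = tab$estimate[m] - baseline$estimate)
    )
  }
  out
}
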