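#' Run the complete stepwise Mendelian randomization pipeline
#'
#' Executes, in order: lipid preparation, EWAS per lipid (per-cohort scan,
#' genomic control, fixed-effect meta-analysis, FDR), polygenic-score
#' construction and instrument validation, the stepwise MR (forward MR,
#' cis PS-SNP check, reverse MR via top meQTLs, multivariable MR, Egger
#' regression), adjudication, and the methylation-expression cis
#' association for CpGs receiving a final causal call. Optionally writes
#' every stage table as TSV plus a `run.json` summary.
#'
#' @param study A `lipid_study` (from [simulate_study] or [read_study]).
#' @param out_dir Optional output directory for stage TSVs.
#' @param alpha Per-step significance threshold.
#' @param q_threshold EWAS FDR threshold.
#' @param ld_r2 LD exclusion threshold for meQTL instruments.
#' @param impute_cells Impute cell percentages for flagged samples using
#'   the PLS predictor before analysis (default FALSE; the synthetic data
#'   carry measured counts).
#' @return List with `ewas` (per lipid), `instruments` (per lipid
#'   diagnostics), `stepwise` (per lipid), `verdicts` (combined),
#'   `expression` (cis association results), `lambdas`.
#' @export
run_all <- function(study, out_dir = NULL, alpha = 0.05, q_threshold = 0.05,
                    ld_r2 = 0.1, impute_cells = FALSE) {
  lipids <- c("TG", "LDL", "HDL")
  if (impute_cells) study <- impute_study_cells(study)
  ps <- study_polygenic_scores(study)

  # instrument validation on the stacked study (cohort as covariate)
  stacked <- stack_for_validation(study, ps)
  diagnostics <- lapply(lipids, function(tr) {
    validate_instrument(stacked$ps[[tr]], stacked$lipids[[tr]],
                        confounders = stacked$confounders,
                        covariates = stacked$covariates)
  })
  names(diagnostics) <- lipids

  ewas <- lapply(lipids, function(tr) run_ewas(study, tr))
  names(ewas) <- lipids
  for (tr in lipids) ewas[[tr]]$significant <- ewas[[tr]]$q < q_threshold

  stepwise <- lapply(lipids, function(tr)
    run_stepwise(study, tr, ewas[[tr]], ps = ps, alpha = alpha, ld_r2 = ld_r2))
  names(stepwise) <- lipids
  verdicts <- do.call(rbind, lapply(stepwise, function(s) s$verdicts))
  rownames(verdicts) <- NULL

  expression <- NULL
  final_cpgs <- unique(verdicts$cpg[verdicts$final_call])
  has_rna <- any(vapply(study$cohorts, function(co) !is.null(co$expression),
                        logical(1)))
  if (length(final_cpgs) > 0 && has_rna) {
    pairs <- cis_gene_pairs(
      study$cpg_meta[study$cpg_meta$cpg %in% final_cpgs, , drop = FALSE],
      study$gene_meta)
    if (nrow(pairs) > 0)
      expression <- methylation_expression_assoc(study, pairs)
  }

  lambdas <- lapply(ewas, function(t)
    c(attr(t, "lambda_cohorts"), meta = attr(t, "lambda_meta")))
  out <- list(ewas = ewas, instruments = diagnostics, stepwise = stepwise,
              verdicts = verdicts, expression = expression, lambdas = lambdas)
  if (!is.null(out_dir)) write_run(out, out_dir, study)
  out
}

stack_for_validation <- function(study, ps) {
  lips <- do.call(rbind, lapply(study$cohorts,
                                function(co) prepare_lipids(co$phenotypes)))
  ps_stack <- sapply(c("TG", "LDL", "HDL"), function(tr)
    unlist(lapply(ps, `[[`, tr)), simplify = FALSE)
  ph <- do.call(rbind, lapply(study$cohorts, function(co) {
    p <- co$phenotypes
    p$bisplate <- paste(p$cohort, p$bisplate)  # plate ids are cohort-specific
    p
  }))
  covs <- data.frame(gender = ph$gender, age = ph$age, cohort = factor(ph$cohort))
  conf <- ph[, c("age", "gender", "mono_pct", "lymph_pct", "neut_pct", "BMI")]
  list(ps = ps_stack, lipids = lips, covariates = covs, confounders = conf)
}

impute_study_cells <- function(study) {
  # train on samples with measured counts pooled across cohorts
  feats <- do.call(rbind, lapply(study$cohorts, function(co) co$methylation))
  ph <- do.call(rbind, lapply(study$cohorts, function(co) co$phenotypes))
  measured <- ph$cells_imputed == 0
  model <- train_wbcc(feats[measured, , drop = FALSE],
                      ph[measured, c("neut_pct", "lymph_pct", "mono_pct")],
                      ph$age[measured], ph$gender[measured],
                      max_features = min(2000, ncol(feats)))
  pred <- predict_wbcc(model, feats, ph$age, ph$gender)
  offset <- 0
  for (cn in names(study$cohorts)) {
    n <- nrow(study$cohorts[[cn]]$phenotypes)
    idx <- offset + seq_len(n)
    flag <- study$cohorts[[cn]]$phenotypes$cells_imputed == 1
    study$cohorts[[cn]]$phenotypes$neut_pct[flag] <- pred[idx, 1][flag]
    study$cohorts[[cn]]$phenotypes$lymph_pct[flag] <- pred[idx, 2][flag]
    study$cohorts[[cn]]$phenotypes$mono_pct[flag] <- pred[idx, 3][flag]
    offset <- offset + n
  }
  study
}

write_run <- function(results, out_dir, study) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in names(results$ewas)) {
    utils::write.table(results$ewas[[tr]],
                       file.path(out_dir, paste0("ewas_", tr, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(results$stepwise[[tr]]$forward,
                       file.path(out_dir, paste0("mr_forward_", tr, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(results$stepwise[[tr]]$reverse))
      utils::write.table(results$stepwise[[tr]]$reverse,
                         file.path(out_dir, paste0("mr_reverse_", tr, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(results$stepwise[[tr]]$multivariable))
      utils::write.table(results$stepwise[[tr]]$multivariable,
                         file.path(out_dir, paste0("mr_multivariable_", tr, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(results$verdicts, file.path(out_dir, "verdicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(results$expression))
    utils::write.table(results$expression,
                       file.path(out_dir, "expression_link.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  lam <- do.call(rbind, lapply(names(results$lambdas), function(tr)
    data.frame(lipid = tr, unit = names(results$lambdas[[tr]]),
               lambda = as.numeric(results$lambdas[[tr]]))))
  utils::write.table(lam, file.path(out_dir, "lambda.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    seed = study$config$seed,
    n_total = sum(study$config$n_per_cohort),
    n_cpgs = study$config$n_cpgs,
    n_significant = vapply(results$ewas, function(t) sum(t$significant),
                           numeric(1)),
    n_final_calls = sum(results$verdicts$final_call),
    lambdas = results$lambdas,
    instrument_F = vapply(results$instruments, function(d) d$F, numeric(1)),
    instrument_R2 = vapply(results$instruments, function(d) d$R2, numeric(1)),
    package_version = as.character(utils::packageVersion("lipidmr"))
  )
  jsonlite::write_json(summary, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(results$verdicts, file.path(out_dir, "verdicts.json"),
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(out_dir)
}
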