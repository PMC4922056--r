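#!/usr/bin/env Rscript
# Stage 3 — polygenic-score instruments and their validity.
#
# Applies the SNP QC filter (info >= 0.5, HWE p >= 1e-4, call rate >= 95 %,
# MAF >= 0.05), builds the weighted polygenic score per lipid (oriented to
# trait-increasing alleles, scaled to mean 0 / SD 1), and validates each
# score: partial F and incremental R-squared in the covariate-adjusted
# lipid model on the stacked cohorts, plus a confounder screen. An
# instrument is taken forward when F > 10 and no confounder association
# falls below p = 0.01.

suppressPackageStartupMessages(library(lipidmr))

study <- read_study("results/study")
qc <- snp_qc_filter(study$snp_meta)
cat("SNP QC:", length(qc$retained), "retained,",
    nrow(qc$excluded), "exclusion reasons\n")

ps <- study_polygenic_scores(study)
diag_out <- list()
for (lipid in c("TG", "LDL", "HDL")) {
  ps_stack <- unlist(lapply(ps, `[[`, lipid))
  rows <- do.call(rbind, lapply(study$cohorts,
                                function(co) prepare_lipids(co$phenotypes)))
  ph <- do.call(rbind, lapply(study$cohorts, function(co) co$phenotypes))
  d <- validate_instrument(
    ps_stack, rows[[lipid]],
    confounders = ph[, c("age", "gender", "mono_pct", "lymph_pct",
                         "neut_pct", "BMI")],
    covariates = data.frame(gender = ph$gender, age = ph$age,
                            cohort = factor(ph$cohort)))
  diag_out[[lipid]] <- list(F = d$F, R2 = d$R2, p = d$p,
                            confounder_p = as.list(d$confounder_p),
                            valid = d$valid)
  cat(sprintf("%s score: R2 = %.1f %%, F = %.0f, valid = %s\n",
              lipid, 100 * d$R2, d$F, d$valid))
  per <- do.call(rbind, lapply(names(study$cohorts), function(cn) {
    data.frame(sample = study$cohorts[[cn]]$phenotypes$sample,
               raw = build_polygenic_score(study$cohorts[[cn]]$genotypes,
                                           study$weights, lipid)$raw,
               scaled = ps[[cn]][[lipid]])
  }))
  utils::write.table(per, sprintf("results/ps_%s.tsv", lipid),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
jsonlite::write_json(diag_out, "results/instrument_diagnostics.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
cat("Scores and diagnostics written to results/\n")
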