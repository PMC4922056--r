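#!/usr/bin/env Rscript
# Stage 2 — epigenome-wide association of each lipid with methylation.
#
# Per cohort: covariate-adjusted linear model per CpG (gender, age, cell
# percentages, bisulfite plate, array position), genomic control on the
# t-statistics. Across cohorts: inverse-variance fixed-effect meta-analysis,
# genomic control on the pooled z, Benjamini-Hochberg FDR. Writes
# results/ewas_<lipid>.tsv and results/lambda.tsv.

suppressPackageStartupMessages(library(lipidmr))

study <- read_study("results/study")
lam_rows <- list()
for (lipid in c("TG", "LDL", "HDL")) {
  tab <- run_ewas(study, lipid)
  utils::write.table(tab, sprintf("results/ewas_%s.tsv", lipid),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lam_rows[[lipid]] <- data.frame(
    lipid = lipid,
    unit = c(names(study$cohorts), "meta"),
    lambda = c(attr(tab, "lambda_cohorts"), attr(tab, "lambda_meta")))
  hits <- tab[tab$significant, ]
  cat(sprintf("%s: %d CpGs at q < 0.05; estimates %s %%/SD; meta lambda %.3f\n",
              lipid, nrow(hits),
              if (nrow(hits)) paste0(round(min(hits$estimate_pct_per_sd), 2),
                                     " to ",
                                     round(max(hits$estimate_pct_per_sd), 2))
              else "-",
              attr(tab, "lambda_meta")))
}
utils::write.table(do.call(rbind, lam_rows), "results/lambda.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("EWAS tables written to results/\n")
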