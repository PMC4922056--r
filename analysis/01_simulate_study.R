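#!/usr/bin/env Rscript
# Stage 1 — simulate the multi-cohort study.
#
# Generates a demonstration-scale synthetic study (3 cohorts, 1000 samples,
# 600 CpGs; the full study conditions — 6 cohorts, 3296 samples, 2000 CpGs —
# are the package defaults and are what scripts/acceptance.R runs) and
# writes it to results/study/ as plain-text files. The truth ledger in
# truth.json records each CpG's causal scenario and effect, the ground
# truth against which later stages are judged.

suppressPackageStartupMessages(library(lipidmr))

cfg <- default_sim_config(seed = 20260101,
                          n_per_cohort = c(300L, 350L, 350L),
                          n_cpgs = 600L,
                          n_forward = 15L, n_reverse = 9L,
                          n_meqtl_direct = 9L, n_pleiotropic = 3L,
                          n_confounded = 30L)
study <- simulate_study(cfg)
write_study(study, "results/study")

tr <- table(study$truth$cpgs$scenario)
cat("Simulated", sum(cfg$n_per_cohort), "samples in", length(cfg$n_per_cohort),
    "cohorts;", cfg$n_cpgs, "CpGs:\n")
print(tr)
cat("SNP panel:", nrow(study$snp_meta), "SNPs (",
    sum(study$weights$primary_trait == "TG"), "TG /",
    sum(study$weights$primary_trait == "LDL"), "LDL /",
    sum(study$weights$primary_trait == "HDL"), "HDL score SNPs )\n")
cat("Study written to results/study/\n")
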