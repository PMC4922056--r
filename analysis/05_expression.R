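#!/usr/bin/env Rscript
# Stage 5 — link causal CpGs to gene expression in cis.
#
# For CpGs that survived the stepwise MR, tests the association of
# methylation with logCPM of every gene whose TSS lies within 100 kb
# (covariate-adjusted per cohort on the RNA subset, plus flowcell;
# meta-analyzed). Effects are logCPM per unit beta (0-1).

suppressPackageStartupMessages(library(lipidmr))

study <- read_study("results/study")
verdicts <- utils::read.table("results/verdicts.tsv", sep = "\t", header = TRUE)
final_cpgs <- unique(verdicts$cpg[verdicts$final_call])
if (length(final_cpgs) == 0) {
  cat("No CpG received a final causal call; nothing to link.\n")
  quit(save = "no")
}
pairs <- cis_gene_pairs(
  study$cpg_meta[study$cpg_meta$cpg %in% final_cpgs, , drop = FALSE],
  study$gene_meta)
cat(length(final_cpgs), "causal CpGs;", nrow(pairs), "cis CpG-gene pairs\n")
res <- methylation_expression_assoc(study, pairs)
utils::write.table(res, "results/expression_link.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
truth_g <- study$truth$genes
m <- merge(res, truth_g, by.x = "gene", by.y = "gene", all.x = TRUE)
cat("Associations at p < 0.05:", sum(res$p < 0.05, na.rm = TRUE), "of",
    nrow(res), "\n")
cat(sprintf("Slope recovery on linked genes: mean estimate %.2f vs mean truth %.2f logCPM/beta\n",
            mean(m$estimate[!is.na(m$slope) & m$slope != 0], na.rm = TRUE),
            mean(m$slope[!is.na(m$slope) & m$slope != 0], na.rm = TRUE)))
cat("expression_link.tsv written to results/\n")
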