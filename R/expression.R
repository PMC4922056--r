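#' Enumerate CpG-gene pairs in cis
#'
#' All (CpG, gene) pairs on the same chromosome with |CpG position - TSS|
#' strictly below 100 kb. Strand is used only to locate the TSS (gene start
#' for +, end for - when a `end` column is present; otherwise `tss` is
#' taken as given).
#'
#' @param cpg_meta data.frame (`cpg`, `chrom`, `pos`).
#' @param gene_meta data.frame (`gene`, `chrom`, `tss`, `strand`).
#' @param window Window in bp (default 1e5, strict `<`).
#' @return data.frame: cpg, gene, chrom, distance_bp.
#' @export
cis_gene_pairs <- function(cpg_meta, gene_meta, window = 1e5) {
  if (!"tss" %in% names(gene_meta)) stop("gene_meta needs a tss column")
  out <- merge(cpg_meta, gene_meta, by = "chrom", suffixes = c("_cpg", "_gene"))
  out$distance_bp <- abs(out$pos - out$tss)
  out <- out[out$distance_bp < window, c("cpg", "gene", "chrom", "distance_bp")]
  rownames(out) <- NULL
  out[order(out$cpg, out$distance_bp), ]
}

#' Library-size normalization of counts to logCPM
#'
#' log2((count + 0.5) / (library size + 1) * 1e6).
#'
#' @param counts Sample x gene matrix of nonnegative counts.
#' @return logCPM matrix of the same shape.
#' @export
normalize_expression <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  lib <- rowSums(counts)
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(utils::head(which(lib == 0), 5), collapse = ", "))
  log2(sweep(counts + 0.5, 1, lib + 1, `/`) * 1e6)
}

#' Methylation-expression association for cis pairs
#'
#' Per cohort with expression data, fits the covariate-adjusted linear
#' model of gene logCPM on CpG beta (with flowcell as extra covariate) on
#' the RNA sample subset, then meta-analyzes across cohorts. Effects are in
#' logCPM per unit beta (0-1).
#'
#' @param study A `lipid_study`.
#' @param pairs data.frame from [cis_gene_pairs] (columns `cpg`, `gene`).
#' @return data.frame: cpg, gene, distance_bp, estimate, se, z, p, n;
#'   pairs with constant methylation are skipped with a reason.
#' @export
methylation_expression_assoc <- function(study, pairs) {
  rna <- Filter(function(co) !is.null(co$expression), study$cohorts)
  if (length(rna) == 0) stop("no cohort has expression data")
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    cpg <- pairs$cpg[i]; gene <- pairs$gene[i]
    est <- se <- ns <- numeric(0)
    for (co in rna) {
      idx <- co$rna_samples
      x <- co$methylation[idx, cpg]
      if (stats::sd(x) < 1e-10) next
      ph <- co$phenotypes[idx, , drop = FALSE]
      covs <- cbind(ewas_covariates(ph), flowcell = co$flowcell)
      r <- fast_assoc(co$expression[, gene, drop = FALSE], x, covs)
      est <- c(est, r$estimate); se <- c(se, r$se); ns <- c(ns, r$n)
    }
    if (length(est) == 0)
      return(data.frame(cpg = cpg, gene = gene,
                        distance_bp = pairs$distance_bp[i],
                        estimate = NA_real_, se = NA_real_, z = NA_real_,
                        p = NA_real_, n = 0,
                        note = "skipped: constant methylation"))
    m <- meta_fixed(est, se)
    data.frame(cpg = cpg, gene = gene, distance_bp = pairs$distance_bp[i],
               estimate = m$pooled_estimate, se = m$pooled_se, z = m$z,
               p = m$p, n = sum(ns), note = "")
  })
  do.call(rbind, rows)
}
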