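#' Write a simulated study to a directory of plain-text files
#'
#' Emits per-cohort TSV matrices (`genotypes_<cohort>.tsv`,
#' `methylation_<cohort>.tsv`, `phenotypes_<cohort>.tsv`, optionally
#' `expression_<cohort>.tsv`), shared annotation (`snps.tsv`, `cpgs.bed`
#' in 0-based half-open BED, `genes.tsv`, `gwas_weights.tsv` in long
#' format), the truth ledger (`truth.json`), a config snapshot
#' (`config.yaml`) and a `manifest.json`. Numeric values are written with
#' 17 significant digits so that read-back round-trips exactly.
#'
#' @param study A `lipid_study`.
#' @param directory Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  wtsv <- function(df, file) {
    path <- file.path(directory, file)
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    file
  }
  wmat <- function(M, file) {
    df <- data.frame(sample = rownames(M), as.data.frame(M, check.names = FALSE),
                     check.names = FALSE)
    wtsv(df, file)
  }
  files <- character(0)
  for (cn in names(study$cohorts)) {
    co <- study$cohorts[[cn]]
    files <- c(files, wmat(co$genotypes, paste0("genotypes_", cn, ".tsv")))
    files <- c(files, wmat(co$methylation, paste0("methylation_", cn, ".tsv")))
    ph <- co$phenotypes
    ph$bisplate <- as.character(ph$bisplate)
    ph$position <- as.character(ph$position)
    files <- c(files, wtsv(ph, paste0("phenotypes_", cn, ".tsv")))
    if (!is.null(co$expression)) {
      E <- data.frame(sample = rownames(co$expression),
                      flowcell = as.character(co$flowcell),
                      as.data.frame(co$expression, check.names = FALSE),
                      check.names = FALSE)
      files <- c(files, wtsv(E, paste0("expression_", cn, ".tsv")))
    }
  }
  files <- c(files, wtsv(study$snp_meta, "snps.tsv"))
  bed <- data.frame(chrom = study$cpg_meta$chrom,
                    start = study$cpg_meta$pos - 1L,  # 1-based -> BED half-open
                    end = study$cpg_meta$pos,
                    name = study$cpg_meta$cpg)
  utils::write.table(bed, file.path(directory, "cpgs.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  files <- c(files, "cpgs.bed")
  files <- c(files, wtsv(study$gene_meta, "genes.tsv"))
  wl <- study$weights
  long <- do.call(rbind, lapply(c("TG", "LDL", "HDL"), function(tr) {
    data.frame(snp = wl$snp, trait = tr, es = wl[[paste0("es_", tr)]],
               primary_trait = wl$primary_trait)
  }))
  long <- long[long$es != 0, ]
  files <- c(files, wtsv(long, "gwas_weights.tsv"))
  jsonlite::write_json(study$truth, file.path(directory, "truth.json"),
                       dataframe = "columns", digits = NA, na = "null")
  files <- c(files, "truth.json")
  cfg <- study$config
  cfg$lipid_noise_cor <- as.vector(cfg$lipid_noise_cor)
  cfg$cell_means <- as.vector(cfg$cell_means)
  cfg$cell_sds <- as.vector(cfg$cell_sds)
  yaml::write_yaml(unclass(cfg), file.path(directory, "config.yaml"))
  files <- c(files, "config.yaml")
  manifest <- list(cohorts = names(study$cohorts),
                   has_expression = vapply(study$cohorts,
                                           function(co) !is.null(co$expression),
                                           logical(1)),
                   files = files)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(directory)
}

#' Read a study written by [write_study]
#'
#' @param directory Study directory.
#' @return A `lipid_study` list (truth and config restored from their
#'   snapshots; matrices numeric with sample rownames).
#' @export
read_study <- function(directory) {
  if (!file.exists(file.path(directory, "manifest.json")))
    stop("not a study directory (no manifest.json): ", directory)
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = TRUE)
  rtsv <- function(file)
    utils::read.table(file.path(directory, file), sep = "\t", header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE)
  rmat <- function(file) {
    df <- rtsv(file)
    M <- as.matrix(df[, -1, drop = FALSE])
    rownames(M) <- df$sample
    M
  }
  cohorts <- list()
  for (cn in manifest$cohorts) {
    gf <- paste0("genotypes_", cn, ".tsv")
    if (!file.exists(file.path(directory, gf)))
      stop("missing genotype file: ", file.path(directory, gf))
    co <- list(genotypes = rmat(gf),
               methylation = rmat(paste0("methylation_", cn, ".tsv")),
               phenotypes = rtsv(paste0("phenotypes_", cn, ".tsv")))
    co$phenotypes$bisplate <- factor(co$phenotypes$bisplate)
    co$phenotypes$position <- factor(co$phenotypes$position)
    ef <- paste0("expression_", cn, ".tsv")
    if (file.exists(file.path(directory, ef))) {
      df <- rtsv(ef)
      co$flowcell <- factor(df$flowcell)
      E <- as.matrix(df[, -(1:2), drop = FALSE])
      rownames(E) <- df$sample
      co$expression <- E
      co$rna_samples <- match(df$sample, co$phenotypes$sample)
    }
    cohorts[[cn]] <- co
  }
  bed <- utils::read.table(file.path(directory, "cpgs.bed"), sep = "\t",
                           col.names = c("chrom", "start", "end", "name"))
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  truth$cpgs <- as.data.frame(truth$cpgs, stringsAsFactors = FALSE)
  truth$genes <- as.data.frame(truth$genes, stringsAsFactors = FALSE)
  cfg <- yaml::read_yaml(file.path(directory, "config.yaml"))
  cfg$lipid_noise_cor <- matrix(cfg$lipid_noise_cor, 3, 3,
                                dimnames = list(c("TG", "LDL", "HDL"),
                                                c("TG", "LDL", "HDL")))
  k <- length(cfg$n_per_cohort)
  cfg$cell_means <- matrix(cfg$cell_means, 3, k,
                           dimnames = list(c("mono", "lymph", "neut"), NULL))
  cfg$cell_sds <- matrix(cfg$cell_sds, 3, k,
                         dimnames = list(c("mono", "lymph", "neut"), NULL))
  cfg$scenario_counts <- unlist(cfg$scenario_counts)
  cfg$n_snps <- unlist(cfg$n_snps)
  cfg$n_cross_snps <- unlist(cfg$n_cross_snps)
  cfg$variance_explained <- unlist(cfg$variance_explained)
  cfg$age_effect <- unlist(cfg$age_effect)
  cfg$gender_effect <- unlist(cfg$gender_effect)
  class(cfg) <- "sim_config"
  wl <- rtsv("gwas_weights.tsv")
  snps <- unique(wl$snp)
  wide <- data.frame(snp = snps,
                     primary_trait = wl$primary_trait[match(snps, wl$snp)])
  for (tr in c("TG", "LDL", "HDL")) {
    col <- rep(0, length(snps))
    sel <- wl$trait == tr
    col[match(wl$snp[sel], snps)] <- wl$es[sel]
    wide[[paste0("es_", tr)]] <- col
  }
  structure(
    list(cohorts = cohorts, snp_meta = rtsv("snps.tsv"),
         cpg_meta = data.frame(cpg = bed$name, chrom = bed$chrom, pos = bed$end),
         gene_meta = rtsv("genes.tsv"), weights = wide, truth = truth,
         config = cfg),
    class = "lipid_study"
  )
}
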