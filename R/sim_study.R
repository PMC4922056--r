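#' Simulate hard-call genotype dosages under Hardy-Weinberg proportions
#'
#' Each SNP is drawn as Binomial(2, MAF) per sample, i.e. genotype classes
#' at the Hardy-Weinberg proportions p^2 / 2pq / q^2. Metadata records the
#' realized MAF, an exact-frequency HWE chi-square p-value, call rate 1 and
#' imputation info 1 (directly genotyped, no missingness).
#'
#' @param n Number of samples.
#' @param mafs Vector of minor allele frequencies in (0, 0.5].
#' @param seed Optional seed.
#' @param snp_meta Optional data.frame with columns `snp`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`; generated if missing.
#' @return List with `genotypes` (n x SNP matrix of dosages in 0..2) and
#'   `snp_meta`.
#' @export
simulate_genotypes <- function(n, mafs, seed = NULL, snp_meta = NULL) {
  if (any(mafs <= 0 | mafs > 0.5))
    stop("invalid parameter: MAF must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  m <- length(mafs)
  G <- vapply(mafs, function(p) stats::rbinom(n, 2L, p), numeric(n))
  G <- matrix(G, nrow = n, ncol = m)
  if (is.null(snp_meta)) {
    alleles <- c("A", "C", "G", "T")
    ea <- sample(alleles, m, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), character(1))
    snp_meta <- data.frame(snp = paste0("rs", seq_len(m)),
                           chrom = rep_len(1:22, m),
                           pos = 5e8 + seq_len(m) * 2e6,
                           effect_allele = ea, other_allele = oa)
  }
  colnames(G) <- snp_meta$snp
  snp_meta$maf <- colMeans(G) / 2
  snp_meta$hwe_p <- apply(G, 2, hwe_pvalue)
  snp_meta$call_rate <- 1
  snp_meta$info <- 1
  list(genotypes = G, snp_meta = snp_meta)
}

# one-degree-of-freedom HWE chi-square test on genotype counts
hwe_pvalue <- function(g) {
  n <- length(g)
  counts <- tabulate(g + 1L, nbins = 3L)
  p <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stats::pchisq(sum((counts - e)^2 / e), df = 1, lower.tail = FALSE)
}

#' Simulate white-blood-cell differential percentages
#'
#' Independent truncated normals for monocyte, lymphocyte and neutrophil
#' percentages; draws are rejected until all components are positive and
#' their sum is at most 100. Zero-variance configurations yield constant
#' columns.
#'
#' @param n Number of samples.
#' @param means,sds Length-3 vectors (mono, lymph, neut).
#' @param seed Optional seed.
#' @return data.frame with columns `mono_pct`, `lymph_pct`, `neut_pct`.
#' @export
simulate_cell_counts <- function(n, means = c(7.5, 36, 52), sds = c(1.8, 8, 7.5),
                                 seed = NULL) {
  stopifnot(n >= 1, length(means) == 3, length(sds) == 3)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(k) {
    cbind(stats::rnorm(k, means[1], sds[1]),
          stats::rnorm(k, means[2], sds[2]),
          stats::rnorm(k, means[3], sds[3]))
  }
  out <- draw(n)
  bad <- which(out[, 1] <= 0 | out[, 2] <= 0 | out[, 3] <= 0 | rowSums(out) > 100)
  tries <- 0
  while (length(bad) > 0 && tries < 1000) {
    out[bad, ] <- draw(length(bad))
    bad <- which(out[, 1] <= 0 | out[, 2] <= 0 | out[, 3] <= 0 | rowSums(out) > 100)
    tries <- tries + 1
  }
  if (length(bad) > 0) stop("cell-count rejection sampling failed; check means/sds")
  data.frame(mono_pct = out[, 1], lymph_pct = out[, 2], neut_pct = out[, 3])
}

#' Construct GWAS-style per-SNP lipid weights
#'
#' Draws per-allele effect sizes for the primary trait of each SNP and
#' rescales them so that the total genetic variance (sum of es^2 * 2p(1-p))
#' equals the configured variance explained per lipid. Designated
#' pleiotropic SNPs receive a secondary (cross-trait) effect; the SNP
#' hosting each trait's direct-meQTL CpGs receives an 8-fold weight,
#' mimicking major lipid loci whose single variant carries a large share of
#' the score.
#'
#' @param config A `sim_config`.
#' @param mafs Named MAF vector for all PS SNPs (names = snp ids).
#' @param primary_trait Character vector, per-SNP primary trait.
#' @param cross_snps Named list: for each trait, ids of its SNPs that also
#'   affect the other trait of the TG/HDL pair.
#' @param big_snps Ids of SNPs given the enlarged weight (direct-meQTL loci).
#' @return data.frame with `snp`, `primary_trait`, and effect columns
#'   `es_TG`, `es_LDL`, `es_HDL` (SD units per effect allele).
#' @export
make_gwas_weights <- function(config, mafs, primary_trait,
                              cross_snps = list(), big_snps = character(0)) {
  snps <- names(mafs)
  es <- matrix(0, length(snps), 3, dimnames = list(snps, c("TG", "LDL", "HDL")))
  for (tr in c("TG", "LDL", "HDL")) {
    idx <- which(primary_trait == tr)
    if (length(idx) == 0) next
    raw <- abs(stats::rnorm(length(idx))) + 0.2
    raw[snps[idx] %in% big_snps] <- raw[snps[idx] %in% big_snps] * 8
    v <- sum(raw^2 * 2 * mafs[idx] * (1 - mafs[idx]))
    es[idx, tr] <- raw * sqrt(config$variance_explained[[tr]] / v)
  }
  # cross-trait (pleiotropic) effects within the TG/HDL pair, opposite sign
  for (tr in names(cross_snps)) {
    other <- if (tr == "TG") "HDL" else "TG"
    ids <- cross_snps[[tr]]
    if (length(ids) == 0) next
    raw <- abs(stats::rnorm(length(ids))) + 0.2
    v <- sum(raw^2 * 2 * mafs[ids] * (1 - mafs[ids]))
    es[ids, other] <- -raw * sqrt(config$cross_variance / v)
  }
  data.frame(snp = snps, primary_trait = primary_trait,
             es_TG = es[, "TG"], es_LDL = es[, "LDL"], es_HDL = es[, "HDL"],
             row.names = NULL)
}

# Genome layout: CpGs spaced 3 Mb apart along 22 chromosomes so that cis
# windows never overlap between CpGs; scenario-linked SNPs are placed
# relative to their CpG.
make_cpg_spec <- function(config) {
  counts <- config$scenario_counts
  n_null <- config$n_cpgs - sum(counts)
  scen <- c(rep("forward", counts["forward"]), rep("reverse", counts["reverse"]),
            rep("meqtl_direct", counts["meqtl_direct"]),
            rep("pleiotropic", counts["pleiotropic"]),
            rep("confounded", counts["confounded"]), rep("null", n_null))
  m <- config$n_cpgs
  traits <- rep(c("TG", "LDL", "HDL"), length.out = m)
  idx <- seq_len(m) - 1L
  spec <- data.frame(
    cpg = sprintf("cg%08d", seq_len(m)),
    chrom = (idx %% 22L) + 1L,
    pos = 1e6 + (idx %/% 22L) * 3e6,
    scenario = scen,
    trait = ifelse(scen == "pleiotropic", "HDL", traits),
    baseline = stats::runif(m, 0.10, 0.90),
    effect = 0, reverse_effect = 0, meqtl_effect = 0, direct_effect = 0,
    conf_coef = stats::rnorm(m, 0, 0.003),
    cis_snp = NA_character_, direct_snp = NA_character_,
    noise_sd = config$cpg_noise_sd,
    stringsAsFactors = FALSE
  )
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  # direct-meQTL CpGs carry large per-allele shifts; keep baselines central
  # so truncation stays negligible
  dm0 <- spec$scenario == "meqtl_direct"
  spec$baseline[dm0] <- stats::runif(sum(dm0), 0.20, 0.70)
  f <- spec$scenario %in% c("forward", "pleiotropic")
  spec$effect[f] <- sgn(sum(f)) *
    stats::runif(sum(f), config$forward_effect_range[1], config$forward_effect_range[2])
  r <- spec$scenario == "reverse"
  spec$reverse_effect[r] <- sgn(sum(r)) * config$reverse_effect
  d <- spec$scenario == "meqtl_direct"
  spec$direct_effect[d] <- sgn(sum(d)) * config$direct_effect
  conf <- spec$scenario == "confounded"
  spec$conf_coef[conf] <- sgn(sum(conf)) * config$confounder_strength_dnam
  spec$conf_coef[f] <- sgn(sum(f)) * config$confounder_strength_dnam / 2
  # cis meQTL SNP for every CpG that needs an instrument or a reverse driver
  needs_cis <- spec$scenario %in% c("forward", "pleiotropic", "reverse")
  spec$meqtl_effect[needs_cis] <- sgn(sum(needs_cis)) * config$meqtl_effect
  spec$cis_snp[needs_cis] <- paste0("rs_cis_", which(needs_cis))
  spec
}

# mvn draws with a given correlation among the three lipid noise terms
rmvn_cor <- function(n, sds, cor_mat) {
  L <- chol(cor_mat)
  Z <- matrix(stats::rnorm(n * 3), n, 3) %*% L
  sweep(Z, 2, sds, `*`)
}

#' Simulate lipid phenotypes from genotypes and weights
#'
#' Builds standardized latent lipid traits that are linear in the weighted
#' allele burden (per-trait genetic variance equal to the configured
#' variance explained), a shared cell-composition confounder, age/gender
#' terms and correlated Gaussian noise; then maps latents to measurement
#' scale: TG log-normal, HDL-C and total cholesterol normal, and LDL-C by
#' the Friedewald formula LDL = TC - HDL - TG/2.2 (mmol/L).
#'
#' @param genotypes Sample x SNP dosage matrix (columns named by SNP id).
#' @param weights Weights table from [make_gwas_weights].
#' @param config A `sim_config`.
#' @param covars Optional data.frame with `z_cells`, `z_age`, `gender`,
#'   `nonfasted` (generated as independent standard draws if missing).
#' @param seed Optional seed.
#' @return List with `phenotypes` (TG, TC, HDL, LDL columns) and `latents`
#'   (n x 3 matrix of the standardized latent traits).
#' @export
simulate_lipids <- function(genotypes, weights, config, covars = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  if (!all(weights$snp %in% colnames(genotypes)))
    stop("allele mismatch: weights contain SNPs absent from the genotype matrix")
  if (is.null(covars)) {
    covars <- data.frame(z_cells = stats::rnorm(n), z_age = stats::rnorm(n),
                         gender = stats::rbinom(n, 1, 0.5),
                         nonfasted = stats::rbinom(n, 1, config$nonfasted_fraction))
  }
  lat <- sim_lipid_latents(genotypes, weights, config, covars)
  list(phenotypes = latents_to_lipids(lat, config), latents = lat)
}

sim_lipid_latents <- function(genotypes, weights, config, covars, cohort_shift = c(0, 0, 0)) {
  n <- nrow(genotypes)
  es <- as.matrix(weights[, c("es_TG", "es_LDL", "es_HDL")])
  rownames(es) <- weights$snp
  G <- genotypes[, weights$snp, drop = FALSE] %*% es  # n x 3 genetic components
  gender_c <- (covars$gender - 0.5) * 2
  lat <- matrix(0, n, 3, dimnames = list(NULL, c("TG", "LDL", "HDL")))
  r2 <- config$variance_explained
  cross_var <- c(TG = 0, LDL = 0, HDL = 0)
  if (any(config$n_cross_snps > 0))
    cross_var[c("TG", "HDL")] <- config$cross_variance
  noise_sd <- numeric(3)
  for (j in 1:3) {
    tr <- c("TG", "LDL", "HDL")[j]
    a <- config$age_effect[[tr]]; g <- config$gender_effect[[tr]]
    f <- if (tr == "TG") config$nonfasted_tg_shift else 0
    cl <- config$confounder_strength_lipid
    v <- 1 - r2[[tr]] - cross_var[[tr]] - cl^2 - a^2 - g^2 -
      f^2 * config$nonfasted_fraction * (1 - config$nonfasted_fraction)
    if (v <= 0.05) stop("lipid variance budget exhausted; reduce effect settings")
    noise_sd[j] <- sqrt(v)
    lat[, j] <- G[, j] + cl * covars$z_cells + a * covars$z_age + g * gender_c +
      f * covars$nonfasted + cohort_shift[j]
  }
  lat + rmvn_cor(n, noise_sd, config$lipid_noise_cor)
}

latents_to_lipids <- function(lat, config) {
  TG <- exp(config$tg_meanlog + config$tg_sdlog * lat[, "TG"])
  HDL <- pmax(config$hdl_mean + config$hdl_sd * lat[, "HDL"], 0.2)
  LDL0 <- pmax(config$ldl_mean + config$ldl_sd * lat[, "LDL"], 0.3)
  TC <- LDL0 + HDL + TG / 2.2
  data.frame(TG = TG, TC = TC, HDL = HDL, LDL = TC - HDL - TG / 2.2)
}

#' Simulate methylation beta values under the configured causal scenarios
#'
#' Forward CpGs are linear in the standardized lipid; reverse CpGs are
#' driven by their cis SNP and feed back into the lipid latents (which this
#' function updates and returns); confounded CpGs share the
#' cell-composition driver with lipids but carry no causal arrow;
#' direct-meQTL CpGs depend on a PS SNP dosage; null CpGs are noise.
#' Values are truncated to \[0.001, 0.999\]; a warning is raised when
#' truncation touches more than 5 % of samples at any CpG.
#'
#' @param lipid_latents n x 3 matrix of latent lipid traits (pre-feedback).
#' @param genotypes Dosage matrix including cis and PS SNPs.
#' @param covars data.frame with `z_cells`, `z_age`, `gender`, plus factor
#'   `bisplate`.
#' @param cpg_spec Scenario table from [make_cpg_spec].
#' @param config A `sim_config`.
#' @param seed Optional seed.
#' @return List with `beta` (n x CpG matrix) and `latents` (lipid latents
#'   after reverse-causation feedback; forward effects use these).
#' @export
simulate_methylation <- function(lipid_latents, genotypes, covars, cpg_spec,
                                 config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ok <- cpg_spec$scenario %in%
    c("null", "forward", "reverse", "confounded", "pleiotropic", "meqtl_direct")
  if (!all(ok)) stop("invalid scenario label: ", unique(cpg_spec$scenario[!ok])[1])
  n <- nrow(lipid_latents)
  m <- nrow(cpg_spec)
  gender_c <- (covars$gender - 0.5) * 2
  plates <- as.integer(factor(covars$bisplate))
  n_plate <- max(plates)
  B <- matrix(stats::rnorm(n * m, 0, 1), n, m)
  B <- sweep(B, 2, cpg_spec$noise_sd, `*`)
  B <- sweep(B, 2, cpg_spec$baseline, `+`)
  B <- B + outer(covars$z_cells, cpg_spec$conf_coef)
  B <- B + outer(covars$z_age, stats::rnorm(m, 0, 0.001))
  B <- B + outer(gender_c, stats::rnorm(m, 0, 0.001))
  plate_eff <- matrix(stats::rnorm(n_plate * m, 0, config$plate_effect_sd), n_plate, m)
  B <- B + plate_eff[plates, , drop = FALSE]
  tr_idx <- match(cpg_spec$trait, c("TG", "LDL", "HDL"))
  # genetic terms (cis meQTL and direct PS-SNP effects) are lipid-independent
  for (j in seq_len(m)) {
    if (!is.na(cpg_spec$cis_snp[j]))
      B[, j] <- B[, j] + cpg_spec$meqtl_effect[j] * genotypes[, cpg_spec$cis_snp[j]]
    if (cpg_spec$scenario[j] == "meqtl_direct")
      B[, j] <- B[, j] + cpg_spec$direct_effect[j] * genotypes[, cpg_spec$direct_snp[j]]
  }
  # reverse causation: methylation regenerates the lipid latents
  lat <- lipid_latents
  for (j in which(cpg_spec$scenario == "reverse")) {
    lat[, tr_idx[j]] <- lat[, tr_idx[j]] +
      cpg_spec$reverse_effect[j] * (B[, j] - cpg_spec$baseline[j])
  }
  # forward effects respond to the final (post-feedback) lipid levels
  Lstd <- scale(lat)
  for (j in which(cpg_spec$scenario %in% c("forward", "pleiotropic"))) {
    B[, j] <- B[, j] + cpg_spec$effect[j] * Lstd[, tr_idx[j]]
  }
  n_trunc <- colSums(B < 0.001 | B > 0.999)
  if (any(n_trunc > 0.05 * n))
    warning("effect too large for baseline: truncation exceeds 5 % of samples at ",
            sum(n_trunc > 0.05 * n), " CpG(s)")
  B[B < 0.001] <- 0.001
  B[B > 0.999] <- 0.999
  colnames(B) <- cpg_spec$cpg
  list(beta = B, latents = lat)
}

#' Simulate expression (logCPM) linked to methylation
#'
#' Linked genes are linear in their CpG's beta value with the configured
#' slope plus Gaussian noise; their TSS lies within 100 kb of the CpG.
#' Unlinked genes are placed more than 100 kb from any CpG.
#'
#' @param methylation Sample x CpG beta matrix.
#' @param expression_spec data.frame with `gene`, `linked_cpg` (NA for
#'   unlinked), `slope`, `chrom`, `tss`, `strand`.
#' @param config A `sim_config`.
#' @param covars data.frame with `z_cells`, `z_age`, `gender` columns (small
#'   nuisance effects) and `flowcell` factor.
#' @param seed Optional seed.
#' @return Sample x gene logCPM matrix.
#' @export
simulate_expression <- function(methylation, expression_spec, config, covars,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  linked <- expression_spec$linked_cpg
  if (any(!is.na(linked) & !(linked %in% colnames(methylation))))
    stop("expression_spec links a CpG absent from the methylation matrix")
  n <- nrow(methylation)
  g <- nrow(expression_spec)
  E <- matrix(stats::rnorm(n * g, 0, config$expression_noise_sd), n, g)
  E <- E + config$expression_intercept
  fc <- as.integer(factor(covars$flowcell))
  fc_eff <- stats::rnorm(max(fc), 0, 0.1)
  E <- E + fc_eff[fc]
  E <- E + outer(covars$z_age, stats::rnorm(g, 0, 0.05))
  for (j in seq_len(g)) {
    if (!is.na(linked[j]))
      E[, j] <- E[, j] + expression_spec$slope[j] * methylation[, linked[j]]
  }
  colnames(E) <- expression_spec$gene
  E
}

#' Simulate a complete multi-cohort study
#'
#' Orchestrates genotype, phenotype, methylation and expression generation
#' for every cohort under a shared SNP panel, CpG scenario table and GWAS
#' weight set, and records the full ground truth. Reverse-scenario CpGs
#' feed back into the lipid latents before forward effects are applied, so
#' the realized data contain both causal directions.
#'
#' @param config A `sim_config` (see [default_sim_config]).
#' @return List of class `lipid_study` with elements `cohorts` (each with
#'   `genotypes`, `methylation`, `phenotypes`, optionally `expression`),
#'   `snp_meta`, `cpg_meta`, `gene_meta`, `weights`, `truth`, `config`.
#' @export
simulate_study <- function(config = default_sim_config()) {
  set.seed(config$seed)
  cpg_spec <- make_cpg_spec(config)

  # --- SNP panel: PS SNPs (possibly relocated next to direct-meQTL CpGs) + cis SNPs
  n_ps <- sum(config$n_snps)
  primary <- rep(c("TG", "LDL", "HDL"), times = config$n_snps)
  ps_ids <- paste0("rs_ps_", seq_len(n_ps))
  ps_meta <- data.frame(snp = ps_ids, chrom = rep_len(1:22, n_ps),
                        pos = 5e8 + seq_len(n_ps) * 2e6,
                        stringsAsFactors = FALSE)
  # One high-weight PS SNP per trait (an APOA5-like major lipid locus) hosts
  # that trait's direct-meQTL CpGs in cis: the SNP is relocated to a cluster
  # region and the CpGs are spread around it within 1 Mb, 120 kb apart so
  # their cis windows stay disjoint.
  big_snps <- character(0)
  for (ti in seq_along(c("TG", "LDL", "HDL"))) {
    tr <- c("TG", "LDL", "HDL")[ti]
    dm <- which(cpg_spec$scenario == "meqtl_direct" & cpg_spec$trait == tr)
    if (length(dm) == 0) next
    pick <- which(primary == tr)[1]
    big_snps <- c(big_snps, ps_ids[pick])
    center <- 4e8 + ti * 1e7
    chrom <- 19 + ti
    ps_meta$chrom[pick] <- chrom
    ps_meta$pos[pick] <- center
    k <- seq_along(dm) - ceiling(length(dm) / 2)
    cpg_spec$chrom[dm] <- chrom
    cpg_spec$pos[dm] <- center + 15000 + k * 120000
    cpg_spec$direct_snp[dm] <- ps_ids[pick]
  }
  cis_idx <- which(!is.na(cpg_spec$cis_snp))
  cis_meta <- data.frame(snp = cpg_spec$cis_snp[cis_idx],
                         chrom = cpg_spec$chrom[cis_idx],
                         pos = cpg_spec$pos[cis_idx] + 35000,
                         stringsAsFactors = FALSE)
  snp_meta <- rbind(ps_meta, cis_meta)
  alleles <- c("A", "C", "G", "T")
  snp_meta$effect_allele <- sample(alleles, nrow(snp_meta), replace = TRUE)
  snp_meta$other_allele <- vapply(snp_meta$effect_allele,
                                  function(a) sample(setdiff(alleles, a), 1), character(1))
  mafs <- stats::runif(nrow(snp_meta), 0.05, 0.5)
  names(mafs) <- snp_meta$snp

  cross_snps <- list()
  for (tr in c("TG", "HDL")) {
    ncs <- config$n_cross_snps[[tr]]
    if (ncs > 0) {
      own <- ps_ids[primary == tr]
      cross_snps[[tr]] <- setdiff(own, big_snps)[seq_len(ncs)]
    }
  }
  weights <- make_gwas_weights(config, mafs[ps_ids], primary,
                               cross_snps = cross_snps, big_snps = big_snps)

  # --- genes: one linked gene per forward/pleiotropic CpG + unlinked genes
  hit <- which(cpg_spec$scenario %in% c("forward", "pleiotropic"))
  gene_meta <- data.frame(
    gene = c(sprintf("gene_l%03d", seq_along(hit)),
             sprintf("gene_u%03d", seq_len(config$n_unlinked_genes))),
    chrom = c(cpg_spec$chrom[hit], rep_len(1:22, config$n_unlinked_genes)),
    tss = c(cpg_spec$pos[hit] + 40000, 7.5e8 + seq_len(config$n_unlinked_genes) * 1e6),
    strand = "+",
    linked_cpg = c(cpg_spec$cpg[hit], rep(NA_character_, config$n_unlinked_genes)),
    slope = c(stats::runif(length(hit), config$expression_slope_range[1],
                           config$expression_slope_range[2]),
              rep(0, config$n_unlinked_genes)),
    stringsAsFactors = FALSE
  )

  k <- length(config$n_per_cohort)
  cohort_shifts <- matrix(stats::rnorm(3 * k, 0, config$cohort_shift_sd), k, 3)
  cohorts <- vector("list", k)
  names(cohorts) <- config$cohort_names
  snp_hwe <- matrix(0, nrow(snp_meta), k)

  for (ci in seq_len(k)) {
    n <- config$n_per_cohort[ci]
    gen <- simulate_genotypes(n, mafs, snp_meta = snp_meta)
    snp_hwe[, ci] <- gen$snp_meta$hwe_p
    cells <- simulate_cell_counts(n, means = config$cell_means[, ci],
                                  sds = config$cell_sds[, ci])
    age <- pmin(pmax(stats::rnorm(n, config$age_mean[ci], config$age_sd[ci]), 18), 81)
    gender <- stats::rbinom(n, 1, config$male_fraction[ci])
    nonfasted <- stats::rbinom(n, 1, config$nonfasted_fraction)
    cw <- c(0.1, -0.4, 0.5)
    z_cells <- as.vector(scale(scale(as.matrix(cells)) %*% cw))
    bisplate <- factor(paste0("plate", (seq_len(n) - 1L) %/% 96L + 1L)[sample.int(n)])
    position <- factor(paste0("pos", sample.int(12L, n, replace = TRUE)))
    covars <- data.frame(z_cells = z_cells, z_age = as.vector(scale(age)),
                         gender = gender, nonfasted = nonfasted,
                         bisplate = bisplate, position = position)

    lat0 <- sim_lipid_latents(gen$genotypes, weights, config, covars,
                              cohort_shift = cohort_shifts[ci, ])
    meth <- simulate_methylation(lat0, gen$genotypes, covars, cpg_spec, config)
    B <- meth$beta
    lat <- meth$latents

    pheno <- latents_to_lipids(lat, config)
    pheno$age <- age
    pheno$gender <- gender
    pheno <- cbind(pheno, cells)
    pheno$bisplate <- bisplate
    pheno$position <- position
    pheno$fasting <- 1L - nonfasted
    pheno$cohort <- config$cohort_names[ci]
    pheno$cells_imputed <- stats::rbinom(n, 1, config$imputed_cells_fraction)
    pheno$smoking <- stats::rbinom(n, 1, 0.25)
    pheno$lipid_meds <- stats::rbinom(n, 1, 0.10)
    pheno$BMI <- stats::rnorm(n, 26, 4)
    sample_ids <- sprintf("%s_s%04d", config$cohort_names[ci], seq_len(n))
    rownames(gen$genotypes) <- rownames(B) <- sample_ids
    pheno$sample <- sample_ids

    cohort <- list(genotypes = gen$genotypes, methylation = B,
                   phenotypes = pheno)
    rf <- config$rna_fraction[ci]
    if (rf > 0) {
      rna_n <- round(rf * n)
      rna_samples <- sort(sample.int(n, rna_n))
      flowcell <- factor(paste0("fc", sample.int(4L, rna_n, replace = TRUE)))
      ecov <- data.frame(z_cells = z_cells[rna_samples],
                         z_age = covars$z_age[rna_samples],
                         gender = gender[rna_samples], flowcell = flowcell)
      E <- simulate_expression(B[rna_samples, , drop = FALSE], gene_meta,
                               config, ecov)
      rownames(E) <- sample_ids[rna_samples]
      cohort$expression <- E
      cohort$flowcell <- flowcell
      cohort$rna_samples <- rna_samples
    }
    cohorts[[ci]] <- cohort
  }

  snp_meta$maf <- mafs
  snp_meta$hwe_p <- apply(snp_hwe, 1, min)  # most extreme cohort value
  snp_meta$call_rate <- 1
  snp_meta$info <- 1

  truth_cpg <- cpg_spec[, c("cpg", "scenario", "trait", "baseline", "effect",
                            "reverse_effect", "cis_snp", "meqtl_effect",
                            "direct_snp", "direct_effect", "conf_coef")]
  truth_cpg$confounded <- truth_cpg$scenario == "confounded"
  structure(
    list(cohorts = cohorts, snp_meta = snp_meta,
         cpg_meta = cpg_spec[, c("cpg", "chrom", "pos")],
         gene_meta = gene_meta[, c("gene", "chrom", "tss", "strand")],
         weights = weights,
         truth = list(cpgs = truth_cpg,
                      genes = gene_meta[, c("gene", "linked_cpg", "slope")]),
         config = config),
    class = "lipid_study"
  )
}
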