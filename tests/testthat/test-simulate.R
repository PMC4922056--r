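test_that("genotype simulation respects MAF bounds and HWE proportions", {
  expect_error(simulate_genotypes(10, c(0.2, 0)), "invalid parameter")
  expect_error(simulate_genotypes(10, 0.6), "invalid parameter")

  g <- simulate_genotypes(10000, 0.5, seed = 40)$genotypes[, 1]
  freq <- tabulate(g + 1L, 3) / 10000
  se3 <- 3 * sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / 10000)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < se3))

  # mean dosage approximates 2*MAF within 3 binomial SEs
  g2 <- simulate_genotypes(10000, 0.2, seed = 41)$genotypes[, 1]
  se <- sqrt(2 * 0.2 * 0.8 / 10000)
  expect_lt(abs(mean(g2) - 0.4), 3 * se)
})

test_that("simulated SNPs pass the HWE test at alpha 0.001 in >= 99 % of SNPs", {
  sim <- simulate_genotypes(2000, runif(500, 0.05, 0.5), seed = 42)
  expect_gte(mean(sim$snp_meta$hwe_p >= 0.001), 0.99)
})

test_that("cell-count simulation produces positive bounded percentages", {
  one <- simulate_cell_counts(1, seed = 43)
  expect_true(all(one > 0))
  big <- simulate_cell_counts(5000, seed = 44)
  expect_true(all(rowSums(big) <= 100))
  # with headroom below the sum constraint, truncation is negligible and the
  # realized mean sits within 3 sampling SEs of the configured mean
  free <- simulate_cell_counts(5000, means = c(6, 30, 44), sds = c(1.5, 6, 6),
                               seed = 44)
  expect_lt(abs(mean(free$neut_pct) - 44), 3 * 6 / sqrt(5000))
  # zero-variance config yields constant columns
  const <- simulate_cell_counts(10, means = c(7, 35, 52), sds = c(0, 0, 0))
  expect_true(all(apply(const, 2, sd) == 0))
})

test_that("null genetic weights leave lipids uncorrelated with the allele burden", {
  cfg <- default_sim_config(preset = "forward-only", seed = 45,
                            variance_explained = c(TG = 0, LDL = 0, HDL = 0))
  sim <- simulate_genotypes(3000, runif(30, 0.1, 0.5), seed = 45)
  w <- data.frame(snp = sim$snp_meta$snp, primary_trait = "TG",
                  es_TG = 0, es_LDL = 0, es_HDL = 0)
  lp <- simulate_lipids(sim$genotypes, w, cfg, seed = 46)
  burden <- as.vector(sim$genotypes %*% rep(1, 30))
  for (tr in c("TG", "LDL", "HDL"))
    expect_lt(cor(burden, lp$latents[, tr])^2, 3 / sqrt(3000))
})

test_that("Friedewald identity holds exactly for every simulated sample", {
  st <- tiny_study(seed = 47, n_per_cohort = c(80, 90))
  for (co in st$cohorts) {
    ph <- co$phenotypes
    expect_equal(ph$LDL, ph$TC - ph$HDL - ph$TG / 2.2, tolerance = 0)
  }
})

test_that("realized polygenic-score R2 converges to the configured value", {
  cfg <- default_sim_config(preset = "forward-only", seed = 48)
  sim <- simulate_genotypes(50000, runif(30, 0.05, 0.5), seed = 48)
  w <- make_gwas_weights(cfg, setNames(sim$snp_meta$maf, sim$snp_meta$snp),
                         rep("TG", 30))
  lp <- simulate_lipids(sim$genotypes, w, cfg, seed = 49)
  ps <- build_polygenic_score(sim$genotypes, w, "TG")
  r2 <- cor(ps$scaled, log(lp$phenotypes$TG))^2
  expect_lt(abs(r2 - 0.056), 0.01)
})

test_that("methylation scenarios produce the configured structure", {
  cfg <- default_sim_config(seed = 50, n_per_cohort = c(200, 200))
  # zero-noise null CpG is constant at its baseline
  spec <- data.frame(cpg = "cgX", chrom = 1, pos = 1e6, scenario = "null",
                     trait = "TG", baseline = 0.5, effect = 0,
                     reverse_effect = 0, meqtl_effect = 0, direct_effect = 0,
                     conf_coef = 0, cis_snp = NA_character_,
                     direct_snp = NA_character_, noise_sd = 0)
  cfg0 <- cfg; cfg0$plate_effect_sd <- 0
  covars <- data.frame(z_cells = rep(0, 50), z_age = 0, gender = 0.5,
                       bisplate = factor(rep("p1", 50)))
  lat <- matrix(0, 50, 3, dimnames = list(NULL, c("TG", "LDL", "HDL")))
  lat[] <- rnorm(150)
  B <- simulate_methylation(lat, matrix(0, 50, 0), covars, spec, cfg0, seed = 51)
  expect_equal(unname(B$beta[, 1]), rep(0.5, 50))

  # oversized effect near the boundary triggers the truncation warning
  spec2 <- spec
  spec2$scenario <- "forward"; spec2$baseline <- 0.98
  spec2$effect <- 0.15; spec2$noise_sd <- 0.02
  expect_warning(
    simulate_methylation(lat, matrix(0, 50, 0), covars, spec2, cfg0, seed = 52),
    "truncation")
  expect_error(
    simulate_methylation(lat, matrix(0, 50, 0), covars,
                         transform(spec, scenario = "bogus"), cfg0),
    "invalid scenario")
})

test_that("the whole simulation is reproducible bit-for-bit under a fixed seed", {
  cfg <- default_sim_config(seed = 53, n_per_cohort = c(60, 70), n_cpgs = 50,
                            n_forward = 3, n_reverse = 2, n_meqtl_direct = 1,
                            n_pleiotropic = 1, n_confounded = 3)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$cohorts[[1]]$methylation, b$cohorts[[1]]$methylation)
  expect_identical(a$cohorts[[2]]$genotypes, b$cohorts[[2]]$genotypes)
  expect_identical(a$cohorts[[1]]$phenotypes, b$cohorts[[1]]$phenotypes)
  expect_identical(a$truth, b$truth)
})

test_that("expression is linear in the linked CpG and respects the cis window", {
  st <- tiny_study(seed = 54, n_per_cohort = c(100, 100))
  # noiseless regeneration recovers the exact slope
  cfg0 <- st$config; cfg0$expression_noise_sd <- 0
  gm <- merge(st$gene_meta, st$truth$genes, by = "gene")
  gm <- gm[!is.na(gm$linked_cpg), ][1, ]
  co <- st$cohorts[[1]]
  covars <- data.frame(z_cells = rep(0, nrow(co$methylation)), z_age = 0,
                       gender = 0.5, flowcell = factor("fc1"))
  spec <- data.frame(gene = gm$gene, linked_cpg = gm$linked_cpg,
                     slope = -5.1, chrom = gm$chrom, tss = gm$tss, strand = "+")
  E <- simulate_expression(co$methylation, spec, cfg0, covars, seed = 55)
  fit <- lm(E[, 1] ~ co$methylation[, gm$linked_cpg])
  expect_equal(unname(coef(fit)[2]), -5.1, tolerance = 1e-8)
  expect_error(
    simulate_expression(co$methylation,
                        transform(spec, linked_cpg = "cg_not_there"),
                        cfg0, covars),
    "absent")
  # linked genes are annotated within 100 kb of their CpG
  linked <- st$truth$genes[!is.na(st$truth$genes$linked_cpg), ]
  pos <- st$cpg_meta$pos[match(linked$linked_cpg, st$cpg_meta$cpg)]
  tss <- st$gene_meta$tss[match(linked$gene, st$gene_meta$gene)]
  expect_true(all(abs(pos - tss) < 1e5))
})
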