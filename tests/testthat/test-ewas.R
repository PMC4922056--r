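test_that("lipid preparation log-transforms TG, derives LDL and standardizes", {
  set.seed(80)
  ph <- data.frame(TG = exp(rnorm(50, 0.4, 0.5)), HDL = rnorm(50, 1.4, 0.3),
                   TC = rnorm(50, 5, 0.8))
  prep <- prepare_lipids(ph)
  for (j in names(prep)) {
    expect_equal(mean(prep[[j]]), 0, tolerance = 1e-12)
    expect_equal(sd(prep[[j]]), 1, tolerance = 1e-12)
  }
  # derived LDL equals explicitly supplied Friedewald LDL (TC 5, HDL 1.5,
  # TG 2.2 -> LDL 2.5)
  ph$LDL <- ph$TC - ph$HDL - ph$TG / 2.2
  expect_equal(prepare_lipids(ph)$LDL, prep$LDL, tolerance = 1e-12)
  expect_equal((5 - 1.5 - 2.2 / 2.2), 2.5)
  # TG ordering is preserved through the log transform
  expect_equal(order(prep$TG), order(ph$TG))

  expect_error(prepare_lipids(transform(ph, TG = 0 * TG)), "non-positive")
  expect_error(prepare_lipids(transform(ph, HDL = 1.4)), "constant")
})

test_that("cohort EWAS recovers a forward effect and reports it in %/SD", {
  st <- tiny_study(seed = 81, n_per_cohort = c(600, 600))
  truth <- st$truth$cpgs
  tab <- run_ewas(st, "TG")
  fwd <- truth[truth$scenario == "forward" & truth$trait == "TG", ]
  m <- match(fwd$cpg, tab$cpg)
  # estimates within 4 SE of the true beta-per-SD effect
  expect_true(all(abs(tab$estimate[m] - fwd$effect) < 4 * tab$se[m]))
  expect_equal(tab$estimate_pct_per_sd, tab$estimate * 100, tolerance = 1e-12)
  # forward CpGs with ~1-2 %/SD effects are overwhelmingly significant here
  expect_gt(mean(tab$significant[m]), 0.7)
})

test_that("EWAS statistics are invariant to affine rescaling of covariates", {
  st <- tiny_study(seed = 82, n_per_cohort = c(150, 150), n_cpgs = 60,
                   n_forward = 3, n_reverse = 2, n_meqtl_direct = 1,
                   n_pleiotropic = 1, n_confounded = 3)
  co <- st$cohorts[[1]]
  a <- run_ewas_cohort(co, "TG")
  co2 <- co
  co2$phenotypes$age <- co2$phenotypes$age * 12 + 100
  co2$phenotypes$mono_pct <- co2$phenotypes$mono_pct / 100
  b <- run_ewas_cohort(co2, "TG")
  expect_equal(a$estimate, b$estimate, tolerance = 1e-9)
  expect_equal(a$p, b$p, tolerance = 1e-9)
})

test_that("zero-variance CpGs are flagged and left out of genomic control", {
  st <- tiny_study(seed = 83, n_per_cohort = c(120, 120), n_cpgs = 60,
                   n_forward = 3, n_reverse = 2, n_meqtl_direct = 1,
                   n_pleiotropic = 1, n_confounded = 3)
  co <- st$cohorts[[1]]
  co$methylation[, 5] <- 0.5
  tab <- run_ewas_cohort(co, "TG")
  expect_true(tab$flagged[5])
  expect_true(is.na(tab$p[5]))
  expect_false(any(tab$flagged[-5]))
})

test_that("permuted lipid yields calibrated cohort-level p-values", {
  st <- tiny_study(seed = 84, n_per_cohort = c(500), n_cpgs = 1000,
                   preset = "null")
  co <- st$cohorts[[1]]
  set.seed(85)
  perm <- sample.int(nrow(co$phenotypes))
  co$phenotypes[, c("TG", "TC", "HDL", "LDL")] <-
    co$phenotypes[perm, c("TG", "TC", "HDL", "LDL")]
  tab <- run_ewas_cohort(co, "TG", apply_gc = FALSE)
  expect_gt(mean(tab$p < 0.05, na.rm = TRUE), 0.03)
  expect_lt(mean(tab$p < 0.05, na.rm = TRUE), 0.07)
})

test_that("meta-analysis pools, controls inflation and keeps q >= p", {
  st <- tiny_study(seed = 86, n_per_cohort = c(200, 250, 200))
  tabs <- lapply(st$cohorts, run_ewas_cohort, lipid = "TG")
  meta <- meta_ewas(tabs, cpg_meta = st$cpg_meta)
  expect_true(all(meta$q >= meta$p))
  # re-scoring the emitted z gives lambda exactly 1 when correction applied
  lam <- attr(meta, "lambda_meta")
  rescore <- suppressWarnings(genomic_control(meta$z)$lambda)
  if (lam > 1) expect_equal(rescore, 1.0, tolerance = 1e-12)
  else expect_equal(rescore, lam, tolerance = 1e-12)
  # duplicated cohorts leave the pooled estimate unchanged
  meta2 <- meta_ewas(c(tabs, tabs), cpg_meta = st$cpg_meta)
  expect_equal(meta2$estimate, meta$estimate, tolerance = 1e-10)
  expect_equal(meta2$sign_consistency, 2L * meta$sign_consistency)
})

test_that("cell-count adjustment is what protects confounded CpGs", {
  st <- tiny_study(seed = 87, n_per_cohort = c(700),
                   confounder_strength_dnam = 0.012)
  co <- st$cohorts[[1]]
  truth <- st$truth$cpgs
  conf_cpgs <- truth$cpg[truth$scenario == "confounded"]
  x <- prepare_lipids(co$phenotypes)$TG
  full <- fast_assoc(co$methylation[, conf_cpgs], x,
                     ewas_covariates(co$phenotypes))
  bare <- fast_assoc(co$methylation[, conf_cpgs], x,
                     co$phenotypes[, c("gender", "age", "bisplate", "position")])
  # with cells in the model the confounded CpGs are near-null;
  # without them the statistics inflate visibly
  expect_lt(median(abs(full$statistic)), median(abs(bare$statistic)))
  expect_gt(mean(bare$p < 0.05), mean(full$p < 0.05))
})

test_that("sensitivity re-runs behave as no-ops or calibrated perturbations", {
  st <- tiny_study(seed = 88, n_per_cohort = c(250, 250), n_cpgs = 100,
                   n_forward = 5, n_reverse = 2, n_meqtl_direct = 1,
                   n_pleiotropic = 1, n_confounded = 5)
  base <- run_ewas(st, "TG")
  # an option that excludes nobody reproduces the baseline exactly
  for (cn in names(st$cohorts)) st$cohorts[[cn]]$phenotypes$fasting <- 1L
  sens <- sensitivity_ewas(st, "TG", options = "fasted_only", baseline = base)
  expect_equal(sens$fasted_only$delta$delta, rep(0, nrow(base)),
               tolerance = 1e-12)
  # BMI is independent noise: adding it barely moves the estimates
  sens2 <- sensitivity_ewas(st, "TG", options = "+BMI", baseline = base)
  expect_lt(abs(mean(sens2$`+BMI`$delta$delta)), 1e-3)
  expect_error(
    sensitivity_ewas(st, "TG", options = "bogus"), "arg")
})
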