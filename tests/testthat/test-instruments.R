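test_that("SNP QC applies the four removal rules with strict inequalities", {
  meta <- data.frame(
    snp = paste0("s", 1:6),
    info = c(0.4, 1, 1, 1, 1, 0.5),
    hwe_p = c(1, 1e-5, 1, 1, 1, 1e-4),
    call_rate = c(1, 1, 0.9, 1, 1, 0.95),
    maf = c(0.3, 0.3, 0.3, 0.04, 0.3, 0.05)
  )
  res <- snp_qc_filter(meta)
  expect_setequal(res$retained, c("s5", "s6"))  # s6 sits exactly on every boundary
  expect_equal(res$excluded$reason[res$excluded$snp == "s4"], "maf")
  expect_setequal(res$excluded$snp, c("s1", "s2", "s3", "s4"))
  # idempotence
  again <- snp_qc_filter(meta[meta$snp %in% res$retained, ])
  expect_setequal(again$retained, res$retained)
  expect_error(snp_qc_filter(meta[, -2]), "info")
})

test_that("dosage computation handles hard calls and class probabilities", {
  expect_equal(compute_dosage(c(0, 1, 2)), c(0, 1, 2))
  expect_equal(compute_dosage(matrix(c(0.2, 0.5, 0.3), 1)), 1.1)
  expect_equal(compute_dosage(matrix(c(1, 0, 0), 1)), 0)
  expect_error(compute_dosage(matrix(c(0.5, 0.2, 0.2), 1)), "sum to 1")
  expect_error(compute_dosage(c(0, 3)), "\\[0, 2\\]")
})

test_that("polygenic score follows the weighted-burden formula and scaling", {
  D <- matrix(c(1, 2), 2, 2)
  colnames(D) <- c("a", "b")
  w <- data.frame(snp = c("a", "b"), primary_trait = "TG",
                  es_TG = c(0.1, 0.3), es_LDL = 0, es_HDL = 0)
  D2 <- rbind(c(1, 1), c(2, 2)); colnames(D2) <- c("a", "b")
  ps <- build_polygenic_score(D2, w, "TG")
  # raw = (d*0.1 + d*0.3) / 0.2 = 2d
  expect_equal(ps$raw, c(2, 4))
  expect_equal(mean(ps$scaled), 0, tolerance = 1e-12)
  expect_equal(sd(ps$scaled), 1, tolerance = 1e-12)

  # single SNP: the effect size cancels, raw equals dosage
  w1 <- w[1, ]
  ps1 <- build_polygenic_score(D2, w1, "TG")
  expect_equal(ps1$raw, D2[, "a"])

  # direct substitution: dosages (1, 2), ES (0.1, 0.3) -> (0.1+0.6)/0.2 = 3.5
  D3 <- rbind(c(1, 2), c(0, 1), c(2, 0)); colnames(D3) <- c("a", "b")
  expect_equal(build_polygenic_score(D3, w, "TG")$raw[1], 3.5)
})

test_that("score is invariant to weight rescaling and allele flips", {
  set.seed(70)
  sim <- simulate_genotypes(200, runif(8, 0.1, 0.5))
  w <- data.frame(snp = sim$snp_meta$snp, primary_trait = "TG",
                  es_TG = rnorm(8, 0.3, 0.1), es_LDL = 0, es_HDL = 0)
  a <- build_polygenic_score(sim$genotypes, w, "TG")
  w2 <- w; w2$es_TG <- 2 * w$es_TG
  expect_equal(build_polygenic_score(sim$genotypes, w2, "TG")$raw, a$raw,
               tolerance = 1e-12)
  # flip one SNP: dosage -> 2 - d, effect sign flips; scaled score unchanged
  G3 <- sim$genotypes; G3[, 3] <- 2 - G3[, 3]
  w3 <- w; w3$es_TG[3] <- -w$es_TG[3]
  expect_equal(build_polygenic_score(G3, w3, "TG")$scaled, a$scaled,
               tolerance = 1e-12)
  expect_error(build_polygenic_score(sim$genotypes[, -1], w, "TG"),
               "absent")
})

test_that("instrument diagnostics match the partial-F oracle", {
  set.seed(71)
  n <- 1500
  z <- rnorm(n)
  lipid <- sqrt(0.05) * z + sqrt(0.95) * rnorm(n)
  age <- rnorm(n)
  d <- validate_instrument(z, lipid, covariates = data.frame(age = age))
  small <- lm(lipid ~ age)
  full <- lm(lipid ~ age + z)
  ref <- anova(small, full)
  expect_equal(d$F, ref$F[2], tolerance = 1e-8)
  expect_equal(d$R2,
               (sum(resid(small)^2) - sum(resid(full)^2)) / sum(resid(small)^2),
               tolerance = 1e-10)
  expect_true(d$valid)

  # degenerate perfect instrument
  dd <- validate_instrument(lipid, lipid)
  expect_equal(dd$R2, 1)
  expect_true(is.infinite(dd$F))

  # confounder screen invalidates an associated instrument
  conf <- z + rnorm(n, 0, 0.5)
  d2 <- validate_instrument(z, lipid, confounders = data.frame(conf = conf))
  expect_lt(d2$confounder_p["conf"], 0.01)
  expect_false(d2$valid)
})
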