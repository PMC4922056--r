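# shared powered study for the step-level scenario tests
mr_study <- local({
  st <- NULL
  function() {
    if (is.null(st)) st <<- tiny_study(seed = 90, n_per_cohort = c(400, 450, 400))
    st
  }
})

test_that("forward MR recovers forward effects and matches EWAS direction", {
  st <- mr_study()
  truth <- st$truth$cpgs
  fwd_cpgs <- truth$cpg[truth$scenario == "forward" & truth$trait == "TG"]
  ewas <- run_ewas(st, "TG")
  mr <- suppressWarnings(mr_forward(st, "TG", fwd_cpgs))
  m <- match(fwd_cpgs, truth$cpg)
  # true effect inside the 95 % CI for most CpGs, concordant signs, wider CIs
  covered <- abs(mr$estimate - truth$effect[m]) < 1.96 * mr$se
  expect_gte(mean(covered), 2 / 3)
  e <- ewas[match(fwd_cpgs, ewas$cpg), ]
  expect_true(all(sign(mr$estimate) == sign(e$estimate)))
  expect_true(all(mr$se > e$se))
})

test_that("forward MR is null on confounded CpGs", {
  st <- mr_study()
  truth <- st$truth$cpgs
  conf <- truth$cpg[truth$scenario == "confounded" & truth$trait == "TG"]
  mr <- suppressWarnings(mr_forward(st, "TG", conf))
  expect_lte(sum(mr$pass), max(1, ceiling(0.3 * length(conf))))
})

test_that("cis PS-SNP check flags direct-meQTL CpGs as mediated", {
  st <- mr_study()
  truth <- st$truth$cpgs
  dm <- truth[truth$scenario == "meqtl_direct", ]
  for (i in seq_len(nrow(dm))) {
    chk <- cis_ps_snp_check(st, dm$trait[i], dm$cpg[i])
    expect_true(chk$applicable)
    expect_true(dm$direct_snp[i] %in% chk$nearby_snps)
    expect_true(chk$mediated)
  }
})

test_that("an inert nearby PS SNP does not trigger mediation", {
  st <- mr_study()
  truth <- st$truth$cpgs
  fwd <- truth[truth$scenario == "forward" & truth$trait == "TG", ][1, ]
  # relocate an inert PS SNP (no direct effect on this CpG) next to it
  inert <- setdiff(st$weights$snp[st$weights$primary_trait == "TG"],
                   truth$direct_snp)[1]
  i <- match(inert, st$snp_meta$snp)
  j <- match(fwd$cpg, st$cpg_meta$cpg)
  st$snp_meta$chrom[i] <- st$cpg_meta$chrom[j]
  st$snp_meta$pos[i] <- st$cpg_meta$pos[j] + 5e5
  chk <- cis_ps_snp_check(st, "TG", fwd$cpg)
  expect_true(chk$applicable)
  expect_false(chk$mediated)
  # a CpG with no PS SNP within 1 Mb auto-passes
  far <- truth[truth$scenario == "forward" & truth$trait == "LDL", ][1, ]
  chk2 <- cis_ps_snp_check(st, "LDL", far$cpg)
  expect_false(chk2$applicable)
  expect_true(chk2$pass)
  expect_match(chk2$reason, "not applicable")
})

test_that("top meQTL selection follows the p-value / distance / position rule", {
  st <- mr_study()
  truth <- st$truth$cpgs
  rev1 <- truth[truth$scenario == "reverse", ][1, ]
  top <- find_top_meqtl(st, rev1$cpg)
  expect_equal(top$snp, rev1$cis_snp)

  # no SNP in cis
  nullcpg <- truth$cpg[truth$scenario == "null"][1]
  expect_match(find_top_meqtl(st, nullcpg)$reason, "no cis SNP")

  # a SNP located in the CpG site is excluded
  st2 <- st
  i <- match(rev1$cis_snp, st2$snp_meta$snp)
  st2$snp_meta$pos[i] <- st2$cpg_meta$pos[match(rev1$cpg, st2$cpg_meta$cpg)]
  top2 <- find_top_meqtl(st2, rev1$cpg)
  expect_true(rev1$cis_snp %in%
                top2$excluded$snp[top2$excluded$reason == "located in CpG site"])

  # a candidate in LD with a PS SNP is excluded
  st3 <- st
  ps_snp <- st3$weights$snp[1]
  i <- match(ps_snp, st3$snp_meta$snp)
  st3$snp_meta$chrom[i] <- st3$cpg_meta$chrom[match(rev1$cpg, st3$cpg_meta$cpg)]
  st3$snp_meta$pos[i] <- st3$cpg_meta$pos[match(rev1$cpg, st3$cpg_meta$cpg)] + 1000
  for (cn in names(st3$cohorts))  # make the cis SNP a near-copy of the PS SNP
    st3$cohorts[[cn]]$genotypes[, rev1$cis_snp] <-
      st3$cohorts[[cn]]$genotypes[, ps_snp]
  top3 <- find_top_meqtl(st3, rev1$cpg)
  expect_true(rev1$cis_snp %in%
                top3$excluded$snp[top3$excluded$reason == "LD with PS SNP"])
})

test_that("reverse MR detects true reverse causation and spares forward CpGs", {
  st <- mr_study()
  truth <- st$truth$cpgs
  rev_cpgs <- truth[truth$scenario == "reverse", ]
  hits <- 0
  for (i in seq_len(nrow(rev_cpgs))) {
    r <- suppressWarnings(
      mr_reverse(st, rev_cpgs$trait[i], rev_cpgs$cpg[i], rev_cpgs$cis_snp[i]))
    hits <- hits + (r$p < 0.05)
    # the estimated direction matches the simulated reverse effect
    if (r$p < 0.05) expect_equal(sign(r$estimate), sign(rev_cpgs$reverse_effect[i]))
  }
  expect_gte(hits / nrow(rev_cpgs), 0.6)

  fwd <- truth[truth$scenario == "forward", ]
  false_hits <- 0
  for (i in seq_len(nrow(fwd))) {
    r <- suppressWarnings(
      mr_reverse(st, fwd$trait[i], fwd$cpg[i], fwd$cis_snp[i]))
    false_hits <- false_hits + (r$p < 0.05)
  }
  expect_lte(false_hits / nrow(fwd), 0.35)
})

test_that("weak meQTL instruments raise a warning", {
  st <- mr_study()
  truth <- st$truth$cpgs
  cpg <- truth$cpg[truth$scenario == "forward"][1]
  null_snp <- st$weights$snp[st$weights$primary_trait == "LDL"][1]  # no effect on cpg
  expect_warning(mr_reverse(st, "TG", cpg, null_snp), "weak meQTL")
})

test_that("multivariable MR attributes single-lipid forward CpGs correctly", {
  st <- mr_study()
  truth <- st$truth$cpgs
  fwd <- truth[truth$scenario == "forward" & truth$trait == "HDL", ][1:2, ]
  for (i in seq_len(nrow(fwd))) {
    mv <- mr_multivariable(st, fwd$cpg[i])
    expect_true(mv$attributed[mv$lipid == "HDL"])
  }
})

test_that("Egger regression over PS SNPs approximates the forward estimate", {
  st <- mr_study()
  truth <- st$truth$cpgs
  fwd <- truth[truth$scenario == "forward" & truth$trait == "HDL", ][1, ]
  egg <- mr_egger_step(st, "HDL", fwd$cpg)
  expect_equal(egg$n_snps, sum(st$weights$primary_trait == "HDL"))
  mr <- suppressWarnings(mr_forward(st, "HDL", fwd$cpg))
  expect_lt(abs(egg$slope - mr$estimate), 3 * sqrt(egg$slope_se^2 + mr$se^2) + 0.003)
  
})

test_that("adjudication applies strict sequential gating", {
  fwd <- data.frame(cpg = c("a", "b", "c"), pass = c(TRUE, FALSE, TRUE),
                    estimate = 0.01)
  cis <- list(a = list(pass = TRUE, reason = "not mediated"),
              b = list(pass = TRUE, reason = "not mediated"),
              c = list(pass = FALSE, reason = "mediated by cis PS SNP rsX"))
  rev <- list(a = data.frame(pass = TRUE), b = data.frame(pass = TRUE),
              c = data.frame(pass = TRUE))
  mv <- list(a = data.frame(lipid = c("TG", "LDL", "HDL"),
                            attributed = c(TRUE, FALSE, FALSE)),
             b = data.frame(lipid = c("TG", "LDL", "HDL"), attributed = FALSE),
             c = data.frame(lipid = c("TG", "LDL", "HDL"), attributed = FALSE))
  egg <- list(a = list(causal = FALSE), b = list(causal = FALSE),
              c = list(causal = FALSE))
  v <- adjudicate("TG", c("a", "b", "c"), fwd, cis, rev, mv, egg)
  expect_true(v$final_call[v$cpg == "a"])
  expect_true(v$method_disagreement[v$cpg == "a"])  # mvMR yes, Egger no
  # step-b failure gates everything downstream
  expect_false(v$step_b[v$cpg == "b"])
  expect_true(is.na(v$step_c[v$cpg == "b"]))
  expect_true(is.na(v$step_e[v$cpg == "b"]))
  # step-c failure gates d and e
  expect_false(v$step_c[v$cpg == "c"])
  expect_true(is.na(v$step_d[v$cpg == "c"]))
  expect_false(v$final_call[v$cpg == "c"])
  expect_match(v$reasons[v$cpg == "c"], "mediated")
})

test_that("batch scans equal their single-CpG counterparts", {
  st <- mr_study()
  truth <- st$truth$cpgs
  cpgs <- truth$cpg[truth$scenario %in% c("forward", "confounded")][1:4]
  ps <- study_polygenic_scores(st)
  mv_batch <- suppressWarnings(lipidmr:::mvmr_scan(st, cpgs, ps))
  egg_batch <- lipidmr:::egger_scan(st, "TG", cpgs)
  for (cpg in cpgs) {
    mv1 <- suppressWarnings(mr_multivariable(st, cpg, ps = ps))
    expect_equal(mv_batch[[cpg]]$estimate, mv1$estimate, tolerance = 1e-8)
    expect_equal(mv_batch[[cpg]]$se, mv1$se, tolerance = 1e-8)
    e1 <- mr_egger_step(st, "TG", cpg)
    expect_equal(egg_batch[[cpg]]$slope, e1$slope, tolerance = 1e-8)
    expect_equal(egg_batch[[cpg]]$pleiotropy_p, e1$pleiotropy_p, tolerance = 1e-8)
  }
})
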