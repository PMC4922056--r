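#' Per-cohort polygenic scores for all three lipids
#'
#' @param study A `lipid_study`.
#' @return Named list (per cohort) of named lists (per trait) of scaled
#'   score vectors.
#' @export
study_polygenic_scores <- function(study) {
  lapply(study$cohorts, function(co) {
    sapply(c("TG", "LDL", "HDL"), function(tr) {
      build_polygenic_score(co$genotypes, study$weights, tr)$scaled
    }, simplify = FALSE)
  })
}

# Vectorized single-instrument, single-exposure 2SLS over outcome columns,
# identical to two_stage_least_squares() per column (asserted in tests).
fast_tsls <- function(Y, exposure, instrument, covariates = NULL) {
  Y <- as.matrix(Y)
  n <- length(exposure)
  C <- build_design(n, covariates)
  qC <- qr(C)
  xr <- qr.resid(qC, exposure)
  zr <- qr.resid(qC, instrument)
  szz <- sum(zr^2)
  gamma1 <- sum(zr * xr) / szz
  xhat <- zr * gamma1
  sxh <- sum(xhat^2)       # equals sum(xhat * xr)
  Yr <- qr.resid(qC, Y)
  Sxy <- as.vector(crossprod(Yr, xr))
  b <- as.vector(crossprod(Yr, xhat)) / sxh
  sxx <- sum(xr^2)
  rss <- pmax(colSums(Yr^2) - 2 * b * Sxy + b^2 * sxx, 0)
  df <- n - qC$rank - 1
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxh)
  stat <- b / se
  df1 <- n - qC$rank - 1
  Fstat <- sxh / ((sxx - sxh) / df1)
  data.frame(outcome = colnames(Y) %||% seq_len(ncol(Y)),
             estimate = b, se = se, statistic = stat,
             p = 2 * stats::pt(-abs(stat), df),
             first_stage_F = Fstat, n = n, df = df, row.names = NULL)
}

# inverse-variance meta over a cpg x cohort grid of estimates/ses
meta_rows <- function(est, se) {
  w <- 1 / se^2
  pooled <- rowSums(w * est) / rowSums(w)
  pooled_se <- 1 / sqrt(rowSums(w))
  z <- pooled / pooled_se
  data.frame(estimate = pooled, se = pooled_se, z = z,
             p = 2 * stats::pnorm(-abs(z)))
}

#' Forward Mendelian randomization: lipid to methylation
#'
#' Per cohort, two-stage least squares with the lipid's scaled polygenic
#' score as instrument and the standard covariates in both stages; results
#' are pooled by fixed-effect meta-analysis per CpG.
#'
#' @param study A `lipid_study`.
#' @param lipid One of "TG", "LDL", "HDL".
#' @param cpg_set Character vector of CpGs to test (typically the
#'   EWAS-significant set).
#' @param ps Optional precomputed [study_polygenic_scores] result.
#' @param alpha Pass threshold on the meta p-value.
#' @return data.frame per CpG: estimate, se, z, p, min first-stage F across
#'   cohorts, total n, `pass`.
#' @export
mr_forward <- function(study, lipid, cpg_set, ps = NULL, alpha = 0.05) {
  if (length(cpg_set) == 0)
    return(data.frame(cpg = character(0), estimate = numeric(0), se = numeric(0),
                      z = numeric(0), p = numeric(0), min_F = numeric(0),
                      n = integer(0), pass = logical(0)))
  if (is.null(ps)) ps <- study_polygenic_scores(study)
  k <- length(study$cohorts)
  est <- se <- matrix(NA_real_, length(cpg_set), k)
  Fs <- numeric(k)
  for (ci in seq_len(k)) {
    co <- study$cohorts[[ci]]
    x <- prepare_lipids(co$phenotypes)[[lipid]]
    r <- fast_tsls(co$methylation[, cpg_set, drop = FALSE], x,
                   ps[[ci]][[lipid]], ewas_covariates(co$phenotypes))
    est[, ci] <- r$estimate
    se[, ci] <- r$se
    Fs[ci] <- r$first_stage_F[1]
  }
  if (any(Fs < 10)) warning("weak instrument: first-stage F below 10 in some cohort")
  m <- meta_rows(est, se)
  data.frame(cpg = cpg_set, m, min_F = min(Fs),
             n = sum(vapply(study$cohorts, function(co) nrow(co$phenotypes), numeric(1))),
             pass = m$p < alpha, row.names = NULL)
}

#' Check for a direct cis effect of polygenic-score SNPs (step c)
#'
#' When one or more PS SNPs lie within 1 Mb of the CpG, the forward MR is
#' re-run with the nearby SNP dosages added as covariates (both stages).
#' The association is called "mediated" by a direct genetic effect when the
#' adjusted meta p-value is no longer significant.
#'
#' @param study A `lipid_study`.
#' @param lipid,cpg Lipid name and CpG id.
#' @param ps Optional precomputed scores.
#' @param window Search window in bp (default 1e6).
#' @param alpha Significance threshold.
#' @param unadjusted_estimate Optional step-b estimate, for the attenuation
#'   fraction.
#' @return List: `applicable`, `nearby_snps`, `p_adjusted`, `estimate_adjusted`,
#'   `mediated`, `pass`, `attenuation`, `reason`.
#' @export
cis_ps_snp_check <- function(study, lipid, cpg, ps = NULL, window = 1e6,
                             alpha = 0.05, unadjusted_estimate = NULL) {
  pos <- study$cpg_meta$pos[match(cpg, study$cpg_meta$cpg)]
  chrom <- study$cpg_meta$chrom[match(cpg, study$cpg_meta$cpg)]
  sm <- study$snp_meta
  near <- sm$snp[sm$snp %in% study$weights$snp &
                   sm$chrom == chrom & abs(sm$pos - pos) <= window]
  if (length(near) == 0)
    return(list(applicable = FALSE, nearby_snps = character(0),
                p_adjusted = NA_real_, estimate_adjusted = NA_real_,
                mediated = FALSE, pass = TRUE, attenuation = NA_real_,
                reason = "not applicable: no PS SNP within window"))
  if (is.null(ps)) ps <- study_polygenic_scores(study)
  k <- length(study$cohorts)
  est <- se <- numeric(k)
  for (ci in seq_len(k)) {
    co <- study$cohorts[[ci]]
    x <- prepare_lipids(co$phenotypes)[[lipid]]
    covs <- cbind(ewas_covariates(co$phenotypes),
                  as.data.frame(co$genotypes[, near, drop = FALSE]))
    r <- suppressWarnings(
      two_stage_least_squares(co$methylation[, cpg], x, ps[[ci]][[lipid]], covs))
    est[ci] <- r$estimate; se[ci] <- r$se
  }
  m <- meta_fixed(est, se)
  med <- m$p >= alpha
  att <- if (!is.null(unadjusted_estimate) && unadjusted_estimate != 0)
    1 - abs(m$pooled_estimate) / abs(unadjusted_estimate) else NA_real_
  list(applicable = TRUE, nearby_snps = near, p_adjusted = m$p,
       estimate_adjusted = m$pooled_estimate, mediated = med, pass = !med,
       attenuation = att,
       reason = if (med) paste("mediated by cis PS SNP", paste(near, collapse = "/"))
                else "not mediated")
}

#' Select the strongest cis meQTL for a CpG (step d instrument)
#'
#' Scans SNPs within 100 kb of the CpG (same chromosome, strict
#' inequality), excluding SNPs located in the CpG site itself (position
#' equal to the C or the G) and SNPs in linkage disequilibrium with any PS
#' SNP above the dosage-correlation R-squared threshold. Each candidate is
#' scored by the covariate-adjusted meta-analyzed association of dosage
#' with methylation; the lowest p-value wins, ties broken by distance then
#' genomic position.
#'
#' @param study A `lipid_study`.
#' @param cpg CpG id.
#' @param window Cis window in bp (default 1e5, strict `<`).
#' @param ld_r2 LD exclusion threshold against PS SNPs.
#' @return List: `snp` (NA if none usable), `p`, `excluded` (data.frame of
#'   snp, reason), `reason` when no instrument.
#' @export
find_top_meqtl <- function(study, cpg, window = 1e5, ld_r2 = 0.1) {
  idx <- match(cpg, study$cpg_meta$cpg)
  pos <- study$cpg_meta$pos[idx]
  chrom <- study$cpg_meta$chrom[idx]
  sm <- study$snp_meta
  cand <- sm[sm$chrom == chrom & abs(sm$pos - pos) < window, , drop = FALSE]
  if (nrow(cand) == 0)
    return(list(snp = NA_character_, p = NA_real_,
                excluded = data.frame(snp = character(0), reason = character(0)),
                reason = "no cis SNP within window"))
  excluded <- data.frame(snp = character(0), reason = character(0))
  in_site <- cand$pos %in% c(pos, pos + 1)
  if (any(in_site))
    excluded <- rbind(excluded, data.frame(snp = cand$snp[in_site],
                                           reason = "located in CpG site"))
  cand <- cand[!in_site, , drop = FALSE]
  ps_snps <- study$weights$snp
  if (nrow(cand) > 0) {
    is_ps <- cand$snp %in% ps_snps
    if (any(is_ps))
      excluded <- rbind(excluded, data.frame(snp = cand$snp[is_ps],
                                             reason = "LD with PS SNP"))
    cand <- cand[!is_ps, , drop = FALSE]
  }
  if (nrow(cand) > 0) {
    # stacked dosage correlation against PS SNPs on the same chromosome
    G <- do.call(rbind, lapply(study$cohorts, function(co)
      co$genotypes[, c(cand$snp, intersect(ps_snps, sm$snp[sm$chrom == chrom])),
                   drop = FALSE]))
    ps_here <- setdiff(colnames(G), cand$snp)
    drop <- logical(nrow(cand))
    if (length(ps_here) > 0) {
      R2 <- stats::cor(G[, cand$snp, drop = FALSE],
                       G[, ps_here, drop = FALSE])^2
      drop <- apply(R2, 1, max) > ld_r2
    }
    if (any(drop))
      excluded <- rbind(excluded, data.frame(snp = cand$snp[drop],
                                             reason = "LD with PS SNP"))
    cand <- cand[!drop, , drop = FALSE]
  }
  if (nrow(cand) == 0)
    return(list(snp = NA_character_, p = NA_real_, excluded = excluded,
                reason = "no usable cis SNP (all excluded)"))
  ps_meta <- vapply(cand$snp, function(s) {
    est <- se <- numeric(length(study$cohorts))
    for (ci in seq_along(study$cohorts)) {
      co <- study$cohorts[[ci]]
      r <- fast_assoc(co$methylation[, cpg, drop = FALSE], co$genotypes[, s],
                      ewas_covariates(co$phenotypes))
      est[ci] <- r$estimate; se[ci] <- r$se
    }
    meta_fixed(est, se)$p
  }, numeric(1))
  dist <- abs(cand$pos - pos)
  ord <- order(ps_meta, dist, cand$pos)
  list(snp = cand$snp[ord[1]], p = ps_meta[ord[1]], excluded = excluded,
       reason = NULL)
}

#' Reverse Mendelian randomization: methylation to lipid (step d)
#'
#' Per cohort, 2SLS with the top cis meQTL dosage instrumenting the CpG's
#' methylation level and the prepared lipid as outcome, meta-analyzed. A
#' non-significant result means no evidence of reverse causation (the CpG
#' passes the step).
#'
#' @param study A `lipid_study`.
#' @param lipid,cpg Lipid name and CpG id.
#' @param meqtl_snp SNP id from [find_top_meqtl].
#' @param alpha Significance threshold.
#' @return data.frame row: estimate (lipid SD per beta unit), se, z, p,
#'   min_F, pass (TRUE = no reverse causation detected).
#' @export
mr_reverse <- function(study, lipid, cpg, meqtl_snp, alpha = 0.05) {
  k <- length(study$cohorts)
  est <- se <- Fs <- numeric(k)
  for (ci in seq_len(k)) {
    co <- study$cohorts[[ci]]
    y <- prepare_lipids(co$phenotypes)[[lipid]]
    r <- fast_tsls(matrix(y, ncol = 1), co$methylation[, cpg],
                   co$genotypes[, meqtl_snp], ewas_covariates(co$phenotypes))
    est[ci] <- r$estimate; se[ci] <- r$se; Fs[ci] <- r$first_stage_F
  }
  if (any(Fs <= 10)) warning("weak meQTL instrument (F <= 10)")
  m <- meta_fixed(est, se)
  data.frame(cpg = cpg, lipid = lipid, snp = meqtl_snp,
             estimate = m$pooled_estimate, se = m$pooled_se, z = m$z, p = m$p,
             min_F = min(Fs), pass = m$p >= alpha, row.names = NULL)
}

#' Multivariable Mendelian randomization over the three lipids (step e)
#'
#' Just-identified 2SLS with TG, LDL-C and HDL-C as joint exposures and
#' their three polygenic scores as instruments (covariates in both stages),
#' per cohort, then fixed-effect meta-analysis per lipid. The CpG's
#' association is attributed to the lipids whose conditional effect is
#' significant.
#'
#' @param study A `lipid_study`.
#' @param cpg CpG id.
#' @param ps Optional precomputed scores.
#' @param alpha Significance threshold.
#' @return data.frame with one row per lipid: estimate, se, z, p,
#'   `attributed`.
#' @export
mr_multivariable <- function(study, cpg, ps = NULL, alpha = 0.05) {
  if (is.null(ps)) ps <- study_polygenic_scores(study)
  k <- length(study$cohorts)
  est <- se <- matrix(NA_real_, 3, k, dimnames = list(c("TG", "LDL", "HDL"), NULL))
  for (ci in seq_len(k)) {
    co <- study$cohorts[[ci]]
    L <- as.matrix(prepare_lipids(co$phenotypes))
    Z <- cbind(TG = ps[[ci]]$TG, LDL = ps[[ci]]$LDL, HDL = ps[[ci]]$HDL)
    r <- suppressWarnings(
      two_stage_least_squares(co$methylation[, cpg], L, Z,
                              ewas_covariates(co$phenotypes)))
    est[, ci] <- r$estimate; se[, ci] <- r$se
  }
  m <- meta_rows(est, se)
  data.frame(cpg = cpg, lipid = rownames(est), m,
             attributed = m$p < alpha, row.names = NULL)
}

#' Egger regression over the polygenic-score SNPs (step e)
#'
#' For every PS SNP of the lipid, the SNP-methylation effect is estimated
#' from the covariate-adjusted dosage model per cohort and meta-analyzed;
#' the SNP-lipid effects are taken from the GWAS weights. Egger regression
#' of the outcome effects on the exposure effects then gives a causal
#' estimate robust to directional pleiotropy, and its intercept tests for
#' net pleiotropy.
#'
#' @param study A `lipid_study`.
#' @param lipid,cpg Lipid name and CpG id.
#' @param alpha Significance threshold.
#' @return List of class `egger_result` (see [egger_regression]) plus
#'   `no_net_pleiotropy` and `causal` flags.
#' @export
mr_egger_step <- function(study, lipid, cpg, alpha = 0.05) {
  w <- study$weights[study$weights$primary_trait == lipid, ]
  es <- w[[paste0("es_", lipid)]]
  keep <- es != 0
  w <- w[keep, ]; es <- es[keep]
  if (nrow(w) < 3) stop("insufficient instruments: fewer than 3 PS SNPs for ", lipid)
  k <- length(study$cohorts)
  bx <- es
  by <- seby <- numeric(nrow(w))
  for (j in seq_len(nrow(w))) {
    est <- se <- numeric(k)
    for (ci in seq_len(k)) {
      co <- study$cohorts[[ci]]
      r <- fast_assoc(co$methylation[, cpg, drop = FALSE],
                      co$genotypes[, w$snp[j]],
                      ewas_covariates(co$phenotypes))
      est[ci] <- r$estimate; se[ci] <- r$se
    }
    m <- meta_fixed(est, se)
    by[j] <- m$pooled_estimate; seby[j] <- m$pooled_se
  }
  out <- egger_regression(bx, by, seby)
  out$no_net_pleiotropy <- out$pleiotropy_p >= alpha
  out$causal <- out$slope_p < alpha && out$no_net_pleiotropy
  out$cpg <- cpg; out$lipid <- lipid
  out
}

# Multivariable 2SLS for many outcome CpGs at once: stage 1 is shared, so
# coefficients for all CpGs come from one linear solve per cohort. Identical
# to mr_multivariable per CpG (asserted in tests).
mvmr_scan <- function(study, cpgs, ps, alpha = 0.05) {
  k <- length(study$cohorts)
  est <- se <- array(NA_real_, c(3, length(cpgs), k))
  for (ci in seq_len(k)) {
    co <- study$cohorts[[ci]]
    n <- nrow(co$phenotypes)
    L <- as.matrix(prepare_lipids(co$phenotypes))
    Z <- cbind(ps[[ci]]$TG, ps[[ci]]$LDL, ps[[ci]]$HDL)
    C <- build_design(n, ewas_covariates(co$phenotypes))
    Xf <- cbind(C, L)
    qZ <- qr(cbind(C, Z))
    Xhat <- qr.fitted(qZ, Xf)
    A <- crossprod(Xhat, Xf)
    Y <- co$methylation[, cpgs, drop = FALSE]
    B <- solve(A, crossprod(Xhat, Y))
    rss <- colSums((Y - Xf %*% B)^2)
    df <- n - ncol(Xf)
    v0 <- diag(solve(crossprod(Xhat)))[ncol(C) + 1:3]
    est[, , ci] <- B[ncol(C) + 1:3, ]
    se[, , ci] <- sqrt(outer(v0, rss / df))
  }
  out <- lapply(seq_along(cpgs), function(j) {
    m <- meta_rows(matrix(est[, j, ], 3), matrix(se[, j, ], 3))
    data.frame(cpg = cpgs[j], lipid = c("TG", "LDL", "HDL"), m,
               attributed = m$p < alpha, row.names = NULL)
  })
  names(out) <- cpgs
  out
}

# Per-SNP methylation effects for all CpGs at once (one scan per SNP and
# cohort), then Egger regression per CpG.
egger_scan <- function(study, lipid, cpgs, alpha = 0.05) {
  w <- study$weights[study$weights$primary_trait == lipid, ]
  es <- w[[paste0("es_", lipid)]]
  keep <- es != 0
  w <- w[keep, ]; es <- es[keep]
  if (nrow(w) < 3) stop("insufficient instruments: fewer than 3 PS SNPs for ", lipid)
  k <- length(study$cohorts)
  by <- vy <- matrix(0, length(cpgs), nrow(w))
  for (j in seq_len(nrow(w))) {
    wsum <- bsum <- numeric(length(cpgs))
    for (ci in seq_len(k)) {
      co <- study$cohorts[[ci]]
      r <- fast_assoc(co$methylation[, cpgs, drop = FALSE],
                      co$genotypes[, w$snp[j]],
                      ewas_covariates(co$phenotypes))
      wt <- 1 / r$se^2
      wsum <- wsum + wt
      bsum <- bsum + wt * r$estimate
    }
    by[, j] <- bsum / wsum
    vy[, j] <- 1 / wsum
  }
  out <- lapply(seq_along(cpgs), function(i) {
    e <- egger_regression(es, by[i, ], sqrt(vy[i, ]))
    e$no_net_pleiotropy <- e$pleiotropy_p >= alpha
    e$causal <- e$slope_p < alpha && e$no_net_pleiotropy
    e$cpg <- cpgs[i]; e$lipid <- lipid
    e
  })
  names(out) <- cpgs
  out
}

#' Run the full stepwise MR for one lipid and adjudicate each CpG
#'
#' Executes steps b (forward MR), c (cis PS-SNP direct-effect check),
#' d (reverse MR via the top cis meQTL) and e (multivariable MR and Egger
#' regression) for every EWAS-significant CpG. All step analyses are
#' computed and recorded (reverse MR in particular is run for every
#' EWAS-identified CpG, not only those surviving earlier steps); the
#' tick/cross verdict applies sequential gating, so steps after the first
#' failure are reported as NA in the verdict table.
#'
#' @param study A `lipid_study`.
#' @param lipid One of "TG", "LDL", "HDL".
#' @param ewas_table Result of [run_ewas] for this lipid.
#' @param ps Optional precomputed scores.
#' @param alpha Per-step significance threshold.
#' @param ld_r2 LD exclusion threshold for meQTL instruments.
#' @param step_bh Apply a per-step Benjamini-Hochberg correction before
#'   thresholding (conservative option; default FALSE).
#' @return List with component tables (`forward`, `cis_check`, `reverse`,
#'   `multivariable`, `egger`) and the `verdicts` data.frame.
#' @export
run_stepwise <- function(study, lipid, ewas_table, ps = NULL, alpha = 0.05,
                         ld_r2 = 0.1, step_bh = FALSE) {
  if (is.null(ps)) ps <- study_polygenic_scores(study)
  sig <- ewas_table$cpg[ewas_table$significant]
  fwd <- suppressWarnings(mr_forward(study, lipid, sig, ps = ps, alpha = alpha))
  if (step_bh && nrow(fwd) > 0) fwd$pass <- bh_fdr(fwd$p) < alpha
  cis <- list(); rev <- list()
  mv <- if (length(sig) > 0) suppressWarnings(mvmr_scan(study, sig, ps, alpha))
        else list()
  egg <- if (length(sig) > 0) egger_scan(study, lipid, sig, alpha) else list()
  for (cpg in sig) {
    b_est <- fwd$estimate[fwd$cpg == cpg]
    cis[[cpg]] <- cis_ps_snp_check(study, lipid, cpg, ps = ps, alpha = alpha,
                                   unadjusted_estimate = b_est)
    top <- find_top_meqtl(study, cpg, ld_r2 = ld_r2)
    if (!is.na(top$snp)) {
      rev[[cpg]] <- suppressWarnings(
        mr_reverse(study, lipid, cpg, top$snp, alpha = alpha))
    } else {
      rev[[cpg]] <- data.frame(cpg = cpg, lipid = lipid, snp = NA_character_,
                               estimate = NA_real_, se = NA_real_, z = NA_real_,
                               p = NA_real_, min_F = NA_real_, pass = NA)
      attr(rev[[cpg]], "reason") <- top$reason
    }
  }
  verdicts <- adjudicate(lipid, sig, fwd, cis, rev, mv, egg, alpha = alpha)
  list(forward = fwd, cis_check = cis, reverse = do.call(rbind, rev),
       multivariable = do.call(rbind, mv), egger = egg, verdicts = verdicts)
}

#' Assemble the tick/cross verdict table for one lipid
#'
#' Step b passes when the forward MR is significant; step c when no nearby
#' PS SNP mediates the association; step d when reverse MR shows no effect
#' of methylation on the lipid (a CpG with no usable cis instrument passes
#' with a note); step e when pleiotropy is excluded by multivariable MR
#' (the lipid's conditional effect remains significant) or by Egger
#' regression (significant slope, non-significant intercept). Steps after
#' the first failure are NA; the final causal call requires all four.
#'
#' @param lipid Lipid name.
#' @param cpgs CpG ids.
#' @param fwd,cis,rev,mv,egg Step outputs as produced by [run_stepwise].
#' @param alpha Significance threshold.
#' @return data.frame: lipid, cpg, step_b..step_e (logical, NA once gated),
#'   final_call, method_disagreement, reasons.
#' @export
adjudicate <- function(lipid, cpgs, fwd, cis, rev, mv, egg, alpha = 0.05) {
  rows <- lapply(cpgs, function(cpg) {
    b <- fwd$pass[fwd$cpg == cpg]
    c_res <- cis[[cpg]]
    d_res <- rev[[cpg]]
    mv_res <- mv[[cpg]]
    e_res <- egg[[cpg]]
    c_pass <- c_res$pass
    d_pass <- if (is.na(d_res$pass)) TRUE else d_res$pass
    mv_attr <- mv_res$attributed[mv_res$lipid == lipid]
    egger_attr <- e_res$causal
    e_pass <- isTRUE(mv_attr) || isTRUE(egger_attr)
    disagreement <- xor(isTRUE(mv_attr), isTRUE(egger_attr))
    reasons <- c(
      if (!b) "no forward MR effect",
      if (b && !c_pass) c_res$reason,
      if (is.na(d_res$pass)) paste0("step d: ", attr(d_res, "reason") %||% "no instrument"),
      if (b && c_pass && d_pass && !e_pass) "pleiotropy not excluded"
    )
    data.frame(
      lipid = lipid, cpg = cpg,
      step_b = b,
      step_c = if (b) c_pass else NA,
      step_d = if (b && c_pass) d_pass else NA,
      step_e = if (b && c_pass && d_pass) e_pass else NA,
      final_call = b && c_pass && d_pass && e_pass,
      method_disagreement = if (b && c_pass && d_pass) disagreement else NA,
      reasons = paste(reasons, collapse = "; "),
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}
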