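---
title: "Stepwise Mendelian randomization of blood lipids and DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise Mendelian randomization of blood lipids and DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmr)
```

## The question and the inferential strategy

An epigenome-wide association study (EWAS) of blood lipids finds CpG sites
whose whole-blood methylation level co-varies with triglycerides (TG), LDL
cholesterol or HDL cholesterol. Such an association is compatible with at
least four causal structures: the lipid alters methylation (forward), the
methylation alters the lipid (reverse), both respond to a shared cause such
as leukocyte composition (confounding), or a genetic variant drives both
(a direct meQTL effect of a score SNP, one form of pleiotropy). `lipidmr`
implements a stepwise Mendelian randomization (MR) framework that
interrogates each of these in turn:

* **Step a — EWAS.** Per cohort, methylation beta at each CpG is regressed
  on the standardized lipid with gender, age, monocyte/lymphocyte/neutrophil
  percentages, bisulfite plate and array position as covariates. Cohort
  t-statistics receive genomic control; cohorts are pooled by
  inverse-variance fixed-effect meta-analysis; the pooled z-statistics
  receive genomic control again and Benjamini–Hochberg FDR selects the CpG
  set (q < 0.05).
* **Step b — forward MR.** Each lipid is instrumented by its weighted
  polygenic score (PS). Two-stage least squares (2SLS) per cohort — stage 1
  regresses the lipid on the PS plus covariates, stage 2 regresses
  methylation on the predicted lipid plus covariates — then fixed-effect
  meta-analysis. Because genotype cannot be caused by methylation, a
  significant effect supports the forward direction free of classical
  confounding.
* **Step c — direct genetic effects.** A score SNP within 1 Mb of the CpG
  might affect methylation directly rather than through the lipid. The 2SLS
  is re-fit with all such SNP dosages as additional covariates; if the
  association vanishes (adjusted meta p ≥ 0.05) it is classed as mediated
  by the cis SNP and the CpG is crossed.
* **Step d — reverse causation.** The strongest cis meQTL (< 100 kb, lowest
  meta p, excluding SNPs located in the CpG site and SNPs in LD with score
  SNPs) instruments methylation with the lipid as outcome. A significant
  reverse estimate crosses the CpG.
* **Step e — pleiotropy.** Two complementary analyses: multivariable MR
  (the three lipids as joint exposures, their three scores as instruments,
  just-identified 2SLS) attributes the effect to the lipids that stay
  conditionally significant; Egger regression of per-SNP methylation
  effects on per-SNP lipid effects estimates the causal slope while its
  intercept tests net directional pleiotropy. The step passes when either
  method supports a non-pleiotropic effect; when they attribute to
  different lipids, both attributions are reported with a disagreement
  flag rather than resolved.

A CpG receives a **final causal call** only when all applicable steps pass.
Step analyses are computed and recorded for every EWAS-significant CpG, but
the tick/cross table gates sequentially: once a step is crossed, later
steps are displayed as not applicable.

## Estimators

All estimators are in `R/stats_*.R` and are deliberately self-contained.

**Covariate-adjusted OLS** (`fit_ols`, with the matrix fast path
`fast_assoc` using Frisch–Waugh–Lovell residualization; the two are
numerically identical and both are tested against explicit
normal-equations oracles).

**Genomic control** (`genomic_control`): λ = median(stat²)/0.4549…, the
median of a 1-df chi-square. When λ > 1 every statistic is divided by √λ,
which makes re-scoring give λ = 1 exactly (a median is equivariant under
scaling); deflation (λ < 1) is not applied. P-values and standard errors
are recomputed from the corrected statistics.

**Fixed-effect meta-analysis** (`meta_fixed`): inverse-variance weights,
normal reference at the meta level, t reference within cohorts. Cohort
effects are simulated homogeneous (intercept shifts only), matching the
fixed-effect model.

**2SLS** (`two_stage_least_squares`): supports multiple exposures and
over-identification; standard errors use the homoskedastic structural
residual (outcome minus *observed*-exposure fit at the 2SLS coefficients),
the conventional default of the IV estimator. The partial F for the
instrument block is reported per exposure; F < 10 raises a weak-instrument
warning, matching the instrument-validity rule (F > 10) used for the
scores. `fast_tsls` and the batch scans `mvmr_scan` / `egger_scan` are
vectorized re-implementations proven equal to the reference path in tests.

**Egger regression** (`egger_regression`): weighted least squares of
SNP–methylation effects on SNP–lipid effects with weights 1/se², exposure
effects oriented positive (flipping the outcome sign), t-tests with n−2 df.
The residual variance is estimated, so balanced pleiotropic overdispersion
is absorbed and the intercept test stays calibrated for exchangeable SNPs;
with strongly heterogeneous SNP precisions and homoskedastic direct
effects the fixed weights are misspecified and the intercept test becomes
mildly anticonservative — a known limitation of the method, stated here
rather than patched.

**MR power** (`mr_power`): analytic power of the 2SLS Wald test from the
non-centrality parameter n·R²·var(x)·b²/var(y − b·x), vectorized; checked
against a 2,000-replicate Monte Carlo 2SLS simulation to within 3
percentage points over a grid of effect sizes and sample sizes.

## The synthetic study

Individual-level multi-omics cohort data of this kind are not publicly
redistributable, so the package ships a generator
(`simulate_study`) whose defaults define the study conditions:

* **Cohorts.** Six cohorts of 164, 748, 785, 692, 184 and 723 samples
  (3,296 total), with cohort-specific age, sex and cell-count
  distributions and per-cohort lipid intercept shifts. Expression is
  available for four cohorts (~62 % of samples), mirroring a typical
  RNA-seq subset.
* **Genotypes.** Hard-call dosages drawn per SNP as Binomial(2, MAF) —
  Hardy–Weinberg proportions by construction; MAF ~ U(0.05, 0.5). The QC
  filter (info ≥ 0.5, HWE p ≥ 1e-4, call rate ≥ 95 %, MAF ≥ 0.05, strict
  removal inequalities) is exercised on metadata.
* **Polygenic scores.** 30 TG, 28 LDL and 60 HDL score SNPs. Per-allele
  effects are drawn and rescaled so the theoretical score R² equals 5.6 %,
  3.1 % and 5.1 % for TG, LDL-C and HDL-C. Ten TG and ten HDL SNPs carry
  opposite-signed cross-trait effects (1 % of variance), the raw material
  for the pleiotropy analyses. One SNP per trait gets an 8-fold weight and
  hosts that trait's direct-meQTL CpGs in cis — the analogue of a major
  lipid locus whose single variant both dominates the score and sits next
  to regulated CpGs. Spreading such weights over many SNPs is impossible
  within the variance budget, which is why the direct-meQTL CpGs cluster
  around one locus per trait.
* **Lipids.** A standardized latent trait per lipid = genetic burden +
  0.2·(cell-composition score) + age and sex terms + correlated noise
  (TG–HDL −0.4, TG–LDL 0.2, LDL–HDL −0.1). TG is log-normal (so the
  log-transform used throughout yields a Gaussian working variable); HDL
  and a latent LDL are normal; total cholesterol is assembled as
  LDL + HDL + TG/2.2 so that the Friedewald formula
  LDL = TC − HDL − TG/2.2 (mmol/L) holds exactly for every sample.
  Non-fasted samples (24 %) receive a small TG shift.
* **Methylation.** Beta values with baseline U(0.1, 0.9), residual SD 0.02,
  small age/sex/bisulfite-plate effects, truncated to [0.001, 0.999] with a
  warning when truncation exceeds 5 % of samples at a CpG. Effects are
  applied on the beta scale because the reported unit (% methylation per SD
  of lipid) is a beta-scale unit. Scenarios:
  * *forward* (and *pleiotropic*, which is forward on HDL while its
    instruments' SNPs also affect TG): effect U(0.010, 0.020) beta/SD with
    random sign — the 1–2 %/SD magnitude typical of lipid EWAS hits;
  * *reverse*: the CpG is driven by its cis SNP (0.03 beta/allele) and
    feeds back into the lipid at 4.5 SD per beta unit (≈ 1 % of lipid
    variance per CpG) — forward effects are applied after the feedback so
    forward CpGs respond to the realized lipid;
  * *confounded*: the cell-composition score moves both the lipid and the
    CpG (1 %/SD on methylation) with no causal arrow;
  * *meqtl_direct*: the CpG is moved 0.06 beta per allele of its host score
    SNP, with central baselines (0.2–0.7) to avoid truncation;
  * *null*: noise (plus negligible random cell-score coefficients).
  Forward-family CpGs also carry a cis meQTL (0.03 beta/allele at 35 kb) so
  that step d has an instrument, as real CpGs almost always do.
* **Expression.** One linked gene per forward/pleiotropic CpG, TSS 40 kb
  from the CpG, logCPM linear in beta with slope U(−5.1, −1.7) and noise
  SD 0.6, plus unlinked genes far away and a flowcell covariate.
* **Cell counts.** Independent truncated normals at cohort-specific means
  and SDs, rejected until positive and summing to ≤ 100. A compositional
  Dirichlet would be more faithful but adds nothing to the confounding
  structure being tested.

The free parameters with no published anchor — confounder strengths (cells→lipid
variance share 0.04; cells→methylation 1 %/SD), the lipid residual
correlations, the meQTL and reverse effect sizes — are not derivable from
published summary tables; they were fixed once at values a lipid
epidemiologist would call realistic and are not tuned. The per-scenario CpG
counts (45 forward, 24 reverse, 30 direct-meQTL, 6 pleiotropic, 60
confounded among 2,000 CpGs) are replicate counts chosen so that recovery
rates are estimable against a ~5 % per-CpG step error.

What the generator does **not** emulate: array probe noise and chip/batch
structure beyond categorical plate/position effects, relatedness and twin
structure, missing genotypes, LD between panel SNPs (LD handling is
exercised in tests by construction), GC bias in counts, and cell-type
heterogeneity beyond the three-percentage summary. Passing tests therefore
demonstrate the statistical logic of the stepwise framework under its own
assumptions, not robustness to those artifacts.

## Numerical and design choices

* Lipids are log-transformed (TG) and standardized **per cohort**, the
  modeling unit of every fit; reported effects are beta × 100, i.e.
  % methylation per SD of lipid.
* The score denominator mean(ES) is taken over effect sizes oriented to the
  trait-increasing allele; unoriented mixed signs could make it ≈ 0. An
  allele flip (dosage → 2 − d, sign flip) leaves the scaled score invariant.
* The confounder screen for instruments warns at p < 0.01 instead of
  hard-failing: a genome-wide score will occasionally brush a confounder
  weakly, and a prominent note is more honest than a binary rejection.
* meQTL tie-breaks are deterministic: lowest p, then smaller distance, then
  lower genomic position. "Located in the CpG site" means SNP position equal
  to the C or the G of the CpG (1-based); BED output is 0-based half-open.
* The LD exclusion threshold for meQTL instruments is dosage-correlation
  R² > 0.1 (configurable); conservative relative to the exemplified 0.52.
* Step thresholds are nominal p < 0.05 with no extra multiple-testing
  within the MR steps, on the argument that the EWAS stage already paid the
  multiplicity cost; `run_stepwise(step_bh = TRUE)` provides the
  conservative per-step BH option.
* Reverse-MR analyses are computed for every EWAS-significant CpG even when
  an earlier step failed, because a pure reverse-causation CpG can never
  pass forward MR (its methylation is independent of the score); gating is
  applied at the verdict, not at the analysis.
* Genomic control treats cohort t-statistics as z (cohort n ≥ 164 makes the
  distinction negligible); λ < 1 is never "corrected up".
* The PLS predictor of cell composition uses NIPALS deflation with
  multivariate response, age and gender appended to the features, a
  two-thirds/one-third train/test split and 5-fold CV; the selected
  component count is the smallest within 0.1 % of the best CV RMSEP.
  Predictions are clipped at 0 but not renormalized (three of five cell
  types are predicted; no sum constraint applies). In the synthetic data
  the methylation matrix encodes cell composition only through a single
  latent score, so held-out correlations are structurally bounded and
  monocytes (smallest loading) are predicted worst — the generator limits
  the ceiling, not the estimator.
* Mean methylation per CpG is reported as the sample-size-weighted pooled
  mean across cohorts.
* The multivariable-MR versus Egger disagreement that can arise for CpGs
  shared between correlated lipids is reported with a flag; the framework
  does not choose a winner.

## Problem sizes

The test suite exercises unit-level properties on small systems and the
end-to-end recovery on the full default study (6 cohorts, 3,296 samples,
2,000 CpGs, seeded), EWAS/MR calibration on 2,000 null CpGs in a two-cohort
null study, Egger calibration on 500 summary-level replicates, the power
oracle on a 3 × 3 grid with 2,000 Monte Carlo replicates per cell, and the
pleiotropy disambiguation on 30 single-cohort replicates of 2,000 samples.
`scripts/acceptance.R` recomputes all of these from scratch at the same
sizes. The numbered scripts under `analysis/` run a reduced demonstration
study (3 cohorts, 1,000 samples, 600 CpGs) so the whole narrative completes
in about a minute.

## Known limitations

* Homoskedastic 2SLS standard errors (no robust option is needed for the
  simulated designs, and none is claimed).
* The Egger intercept test's mild anticonservatism under strongly
  heterogeneous SNP precisions, discussed above.
* Fixed-effect meta-analysis only; no heterogeneity statistics beyond the
  cross-cohort sign-consistency count.
* No trans-meQTL search, no LD clumping or weight re-estimation for the
  scores, no weighted-median or mode-based MR estimators.
* Expression association uses plain per-gene OLS rather than
  moderated/precision-weighted fits; estimates coincide asymptotically,
  small-sample standard errors may differ slightly.
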