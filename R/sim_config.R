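#' Default simulation configuration
#'
#' Builds the configuration object that defines a synthetic multi-cohort
#' study: six cohorts at the characteristic sample sizes of a large
#' population meta-analysis (164, 748, 785, 692, 184, 723; 3296 total),
#' polygenic scores explaining 5.6 / 3.1 / 5.1 % of TG / LDL-C / HDL-C
#' variance, and a CpG panel mixing causal scenarios (null, forward,
#' reverse, confounded, pleiotropic, direct cis-meQTL).
#'
#' @param preset One of `"full-topology"` (all scenarios), `"forward-only"`
#'   (forward + null, no reverse feedback or pleiotropy) or `"null"` (no
#'   true effects at all).
#' @param seed Master seed; every downstream draw flows from it.
#' @param n_per_cohort Integer vector of cohort sizes.
#' @param n_cpgs Total number of CpGs on the synthetic array.
#' @param n_forward,n_reverse,n_meqtl_direct,n_pleiotropic,n_confounded
#'   Scenario counts (remaining CpGs are null). Ignored where the preset
#'   forces them to zero.
#' @param variance_explained Named vector: target PS R-squared per lipid.
#' @param forward_effect_range Absolute forward effects (beta per SD lipid).
#' @param cpg_noise_sd Residual SD of methylation beta values.
#' @param meqtl_effect Per-allele cis-meQTL effect (beta units).
#' @param direct_effect Per-allele direct effect of a PS SNP on its CpG.
#' @param reverse_effect Effect of methylation on lipid (SD per beta unit).
#' @param confounder_strength_lipid SD of lipid per SD of the cell-composition
#'   score (shared confounder).
#' @param confounder_strength_dnam Beta change per SD of the cell score at
#'   confounded CpGs.
#' @param rna_fraction Per-cohort fraction of samples with expression data.
#' @return List of class `sim_config`.
#' @export
default_sim_config <- function(preset = c("full-topology", "forward-only", "null"),
                               seed = 1L,
                               n_per_cohort = c(164L, 748L, 785L, 692L, 184L, 723L),
                               n_cpgs = 2000L,
                               n_forward = 45L,
                               n_reverse = 24L,
                               n_meqtl_direct = 30L,
                               n_pleiotropic = 6L,
                               n_confounded = 60L,
                               variance_explained = c(TG = 0.056, LDL = 0.031, HDL = 0.051),
                               forward_effect_range = c(0.010, 0.020),
                               cpg_noise_sd = 0.02,
                               meqtl_effect = 0.03,
                               direct_effect = 0.06,
                               reverse_effect = 4.5,
                               confounder_strength_lipid = 0.2,
                               confounder_strength_dnam = 0.010,
                               rna_fraction = c(0.97, 0.82, 0.83, 0, 0, 0.86)) {
  preset <- match.arg(preset)
  if (preset == "forward-only") {
    n_reverse <- n_meqtl_direct <- n_pleiotropic <- 0L
  } else if (preset == "null") {
    n_forward <- n_reverse <- n_meqtl_direct <- n_pleiotropic <- 0L
    n_confounded <- 0L
  }
  stopifnot(all(n_per_cohort >= 1),
            all(variance_explained >= 0), all(variance_explained <= 0.5),
            n_forward + n_reverse + n_meqtl_direct + n_pleiotropic + n_confounded <= n_cpgs)
  k <- length(n_per_cohort)
  cohort_names <- paste0("cohort", seq_len(k))
  # cohort-level demographics at the scale of typical adult population cohorts
  rep_k <- function(x) rep_len(x, k)
  cfg <- list(
    preset = preset, seed = as.integer(seed),
    n_per_cohort = as.integer(n_per_cohort), cohort_names = cohort_names,
    n_cpgs = as.integer(n_cpgs),
    scenario_counts = c(forward = n_forward, reverse = n_reverse,
                        meqtl_direct = n_meqtl_direct,
                        pleiotropic = n_pleiotropic, confounded = n_confounded),
    n_snps = c(TG = 30L, LDL = 28L, HDL = 60L),
    n_cross_snps = if (preset == "full-topology") c(TG = 10L, LDL = 0L, HDL = 10L)
                   else c(TG = 0L, LDL = 0L, HDL = 0L),
    cross_variance = 0.01,
    variance_explained = variance_explained,
    forward_effect_range = forward_effect_range,
    cpg_noise_sd = cpg_noise_sd,
    meqtl_effect = meqtl_effect,
    direct_effect = direct_effect,
    reverse_effect = reverse_effect,
    confounder_strength_lipid = confounder_strength_lipid,
    confounder_strength_dnam = confounder_strength_dnam,
    lipid_noise_cor = matrix(c(1, 0.2, -0.4,
                               0.2, 1, -0.1,
                               -0.4, -0.1, 1), 3, 3,
                             dimnames = list(c("TG", "LDL", "HDL"),
                                             c("TG", "LDL", "HDL"))),
    # lipid scale parameters (mmol/L; TG log-normal)
    tg_meanlog = log(1.5), tg_sdlog = 0.5,
    hdl_mean = 1.4, hdl_sd = 0.4,
    ldl_mean = 3.3, ldl_sd = 0.9,
    # covariate effects on the standardized lipid scale
    age_effect = c(TG = 0.15, LDL = 0.15, HDL = -0.05),
    gender_effect = c(TG = 0.10, LDL = 0.05, HDL = -0.15),
    nonfasted_tg_shift = 0.15,
    nonfasted_fraction = 0.24,
    imputed_cells_fraction = 0.15,
    age_mean = rep_k(c(65.6, 45.6, 58.4, 34, 62.4, 67.6)),
    age_sd = rep_k(c(6.8, 13.3, 7.5, 12.1, 9.4, 6.0)),
    male_fraction = rep_k(c(0.50, 0.42, 0.48, 0.32, 0.60, 0.42)),
    cell_means = rbind(mono = rep_k(c(7.9, 8.5, 5.5, 7.7, 6.8, 7.1)),
                       lymph = rep_k(c(51.2, 34.5, 29.2, 35.1, 31.8, 36.3)),
                       neut = rep_k(c(40.7, 53.3, 59.8, 52.6, 55.3, 48.3))),
    cell_sds = rbind(mono = rep_k(c(1.6, 2.2, 1.5, 2.0, 1.1, 2.1)),
                     lymph = rep_k(c(14.0, 7.4, 6.9, 7.8, 7.1, 7.9)),
                     neut = rep_k(c(6.9, 8.0, 7.7, 7.7, 7.0, 7.1))),
    rna_fraction = rep_k(rna_fraction),
    expression_slope_range = c(-5.1, -1.7),
    expression_noise_sd = 0.6,
    expression_intercept = 5,
    n_unlinked_genes = 10L,
    plate_effect_sd = 0.002,
    cohort_shift_sd = 0.15
  )
  class(cfg) <- "sim_config"
  cfg
}
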