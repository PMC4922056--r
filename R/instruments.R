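#' SNP quality-control filter
#'
#' Retains SNPs with imputation info score >= 0.5, Hardy-Weinberg p-value
#' >= 1e-4, call rate >= 95 % and minor allele frequency >= 0.05 (removal
#' uses strict inequalities, so boundary values are kept).
#'
#' @param snp_meta data.frame with columns `snp`, `info`, `hwe_p`,
#'   `call_rate`, `maf`.
#' @return List with `retained` (SNP ids) and `excluded` (data.frame of
#'   snp, reason; one row per failed rule).
#' @export
snp_qc_filter <- function(snp_meta) {
  needed <- c("info", "hwe_p", "call_rate", "maf")
  missing_cols <- setdiff(needed, names(snp_meta))
  if (length(missing_cols) > 0)
    stop("missing QC column(s): ", paste(missing_cols, collapse = ", "))
  fails <- list(
    info = snp_meta$info < 0.5,
    hwe = snp_meta$hwe_p < 1e-4,
    call_rate = snp_meta$call_rate < 0.95,
    maf = snp_meta$maf < 0.05
  )
  excl <- do.call(rbind, lapply(names(fails), function(r) {
    idx <- which(fails[[r]])
    if (length(idx) == 0) return(NULL)
    data.frame(snp = snp_meta$snp[idx], reason = r)
  }))
  if (is.null(excl)) excl <- data.frame(snp = character(0), reason = character(0))
  any_fail <- Reduce(`|`, fails)
  list(retained = snp_meta$snp[!any_fail], excluded = excl)
}

#' Expected allele dosage from genotype calls or class probabilities
#'
#' Dosage = 0*AA + 1*AB + 2*BB. Accepts a vector of hard calls (0/1/2) or a
#' 3-column matrix of genotype-class probabilities (rows must sum to 1
#' within 1e-6).
#'
#' @param genotype Hard-call vector or n x 3 probability matrix (AA, AB, BB).
#' @return Numeric dosage vector with values in \[0, 2\].
#' @export
compute_dosage <- function(genotype) {
  if (is.matrix(genotype) || is.data.frame(genotype)) {
    P <- as.matrix(genotype)
    if (ncol(P) != 3) stop("probability input must have 3 columns (AA, AB, BB)")
    if (any(abs(rowSums(P) - 1) > 1e-6))
      stop("genotype class probabilities must sum to 1")
    as.vector(P %*% c(0, 1, 2))
  } else {
    if (any(genotype < 0 | genotype > 2, na.rm = TRUE))
      stop("hard calls must lie in [0, 2]")
    as.numeric(genotype)
  }
}

#' Weighted polygenic score for one lipid trait
#'
#' Restricts to SNPs whose primary trait matches `trait`, orients every SNP
#' to its trait-increasing allele (flipping dosage to 2 - d where the
#' effect size is negative), computes
#' `raw = sum(dosage_i * ES_i) / mean(ES)`, and scales the score to mean 0,
#' SD 1.
#'
#' @param dosages Sample x SNP dosage matrix (columns named by SNP id).
#' @param weights Weights table (columns `snp`, `primary_trait`, `es_TG`,
#'   `es_LDL`, `es_HDL`).
#' @param trait One of "TG", "LDL", "HDL".
#' @return List of class `polygenic_score` with `raw`, `scaled`, `trait`,
#'   `n_snps`.
#' @export
build_polygenic_score <- function(dosages, weights, trait = c("TG", "LDL", "HDL")) {
  trait <- match.arg(trait)
  w <- weights[weights$primary_trait == trait, ]
  es <- w[[paste0("es_", trait)]]
  keep <- es != 0
  w <- w[keep, ]; es <- es[keep]
  if (nrow(w) == 0) stop("no SNPs with primary trait ", trait)
  if (!all(w$snp %in% colnames(dosages)))
    stop("cannot harmonize: SNP(s) absent from dosage matrix: ",
         paste(setdiff(w$snp, colnames(dosages)), collapse = ", "))
  D <- as.matrix(dosages[, w$snp, drop = FALSE])
  flip <- es < 0
  D[, flip] <- 2 - D[, flip, drop = FALSE]
  es <- abs(es)
  if (mean(es) == 0) stop("degenerate weights: mean effect size is zero")
  raw <- as.vector(D %*% es) / mean(es)
  s <- stats::sd(raw)
  if (s == 0) stop("degenerate score: zero variance across samples")
  structure(
    list(raw = raw, scaled = as.vector(scale(raw)), trait = trait,
         n_snps = nrow(w)),
    class = "polygenic_score"
  )
}

#' Instrument validity diagnostics for a polygenic score
#'
#' Computes the partial F-statistic and incremental R-squared of the score
#' in a covariate-adjusted model of the prepared lipid, and screens the
#' score for association with each supplied confounder. The instrument is
#' flagged valid when F > 10 and no confounder association falls below the
#' screen level.
#'
#' @param ps Scaled polygenic score vector.
#' @param lipid Prepared (log/scaled) lipid vector.
#' @param confounders data.frame of candidate confounders to screen.
#' @param covariates Covariates of the lipid model.
#' @param screen_p Confounder screen level (default 0.01).
#' @return List of class `instrument_diagnostics` with `F`, `R2`, `p`,
#'   `confounder_p` (named vector), `valid`.
#' @export
validate_instrument <- function(ps, lipid, confounders = NULL,
                                covariates = NULL, screen_p = 0.01) {
  n <- length(ps)
  C <- build_design(n, covariates)
  qC <- qr(C)
  e0 <- qr.resid(qC, lipid)
  xr <- qr.resid(qC, ps)
  rss0 <- sum(e0^2)
  sxx <- sum(xr^2)
  if (sxx < 1e-12) {
    F_stat <- Inf; R2 <- 1; p <- 0
  } else {
    b <- sum(xr * e0) / sxx
    rss1 <- rss0 - b^2 * sxx
    df1 <- n - qC$rank - 1
    R2 <- (rss0 - rss1) / rss0
    if (rss1 <= 1e-12 * rss0) {
      F_stat <- Inf; p <- 0
    } else {
      F_stat <- (rss0 - rss1) / (rss1 / df1)
      p <- stats::pf(F_stat, 1, df1, lower.tail = FALSE)
    }
  }
  conf_p <- numeric(0)
  if (!is.null(confounders)) {
    confounders <- as.data.frame(confounders)
    conf_p <- vapply(confounders, function(v) fit_ols(ps, as.numeric(v))$p,
                     numeric(1))
  }
  structure(
    list(F = F_stat, R2 = R2, p = p, confounder_p = conf_p,
         valid = is.infinite(F_stat) || (F_stat > 10 && !any(conf_p < screen_p))),
    class = "instrument_diagnostics"
  )
}
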