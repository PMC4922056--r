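#' Genomic control of association test statistics
#'
#' Computes the inflation factor lambda as the ratio of the median squared
#' statistic to the median of the chi-square distribution with one degree of
#' freedom (0.4549364...), and, when lambda exceeds 1, divides every
#' statistic by sqrt(lambda) so that the corrected set re-scores to lambda
#' exactly 1. Deflation (lambda < 1) is not applied.
#'
#' @param statistics Numeric vector of t- or z-statistics.
#' @return List with `lambda` and `corrected` (the possibly rescaled
#'   statistics).
#' @export
genomic_control <- function(statistics) {
  stats_ok <- statistics[is.finite(statistics)]
  if (length(stats_ok) == 0) stop("no finite statistics supplied")
  if (length(stats_ok) < 100)
    warning("genomic control on fewer than 100 statistics is unstable")
  lambda <- stats::median(stats_ok^2) / stats::qchisq(0.5, df = 1)
  if (lambda == 0) {
    warning("all statistics are zero; genomic control skipped")
    return(list(lambda = 0, corrected = statistics))
  }
  corrected <- if (lambda > 1) statistics / sqrt(lambda) else statistics
  list(lambda = lambda, corrected = corrected)
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' @param estimates Numeric vector of per-study estimates.
#' @param ses Numeric vector of per-study standard errors (> 0).
#' @return List of class `meta_result` with `pooled_estimate`, `pooled_se`,
#'   `z`, `p` (two-sided normal), `k`, and the per-study weights.
#' @export
meta_fixed <- function(estimates, ses) {
  if (length(estimates) == 0) stop("empty input: no studies to pool")
  if (length(estimates) != length(ses)) stop("estimates and ses differ in length")
  if (any(!is.finite(ses)) || any(ses <= 0)) stop("all standard errors must be positive")
  w <- 1 / ses^2
  pooled <- sum(w * estimates) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled / pooled_se
  structure(
    list(pooled_estimate = pooled, pooled_se = pooled_se, z = z,
         p = 2 * stats::pnorm(-abs(z)), k = length(estimates), weights = w),
    class = "meta_result"
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, capped at 1. NaN inputs propagate with a
#' warning.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.nan(pvalues))) warning("NaN p-values propagated as NaN")
  bad <- pvalues[!is.na(pvalues)]
  if (any(bad < 0 | bad > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-stage least squares (single or multivariable)
#'
#' Stage 1 regresses each exposure on the instruments plus covariates;
#' stage 2 regresses the outcome on the predicted exposures plus covariates.
#' Standard errors use the structural residuals (outcome minus
#' observed-exposure fit at the 2SLS coefficients), the conventional
#' homoskedastic IV formula. The partial F-statistic for the instrument
#' block is reported per exposure; F below 10 triggers a weak-instrument
#' warning.
#'
#' @param outcome Numeric outcome vector.
#' @param exposures Numeric vector or matrix (samples x exposures).
#' @param instruments Numeric vector or matrix (samples x instruments); needs
#'   at least as many instruments as exposures.
#' @param covariates Optional covariates entering both stages.
#' @param weak_warning Warn when any first-stage partial F is below 10.
#' @return data.frame of class `mr_result`, one row per exposure, with
#'   `estimate`, `se`, `statistic`, `p`, `first_stage_F`, `first_stage_R2`,
#'   `n`, `df`.
#' @export
two_stage_least_squares <- function(outcome, exposures, instruments,
                                    covariates = NULL, weak_warning = TRUE) {
  X_end <- as.matrix(exposures)
  Z_ins <- as.matrix(instruments)
  n <- length(outcome)
  stopifnot(nrow(X_end) == n, nrow(Z_ins) == n)
  m <- ncol(X_end)
  q <- ncol(Z_ins)
  if (q < m) stop("under-identified: fewer instruments (", q, ") than exposures (", m, ")")
  if (is.null(colnames(X_end))) colnames(X_end) <- paste0("exposure", seq_len(m))
  C <- build_design(n, covariates)
  Z <- cbind(C, Z_ins)
  qZ <- qr(Z)
  if (qZ$rank < qC_rank(C) + m)
    stop("under-identified: instruments collinear with covariates or each other")
  X <- cbind(C, X_end)
  Xhat <- qr.fitted(qZ, X)
  A <- crossprod(Xhat, X)  # equals crossprod(Xhat) up to numerical error
  qa <- qr(A)
  if (qa$rank < ncol(X))
    stop("under-identified: predicted exposures collinear (rank condition fails)")
  beta <- solve(qa, crossprod(Xhat, outcome))
  resid <- outcome - X %*% beta
  df <- n - ncol(X)
  sigma2 <- sum(resid^2) / df
  V <- sigma2 * solve(qr(crossprod(Xhat)))
  idx <- ncol(C) + seq_len(m)
  est <- beta[idx]
  se <- sqrt(diag(V)[idx])
  stat <- est / se
  p <- 2 * stats::pt(-abs(stat), df)

  # first-stage partial F and R2 per exposure
  qC <- qr(C)
  Fs <- R2s <- numeric(m)
  for (j in seq_len(m)) {
    e0 <- qr.resid(qC, X_end[, j])
    e1 <- qr.resid(qZ, X_end[, j])
    rss0 <- sum(e0^2); rss1 <- sum(e1^2)
    df1 <- n - qZ$rank
    Fs[j] <- ((rss0 - rss1) / q) / (rss1 / df1)
    R2s[j] <- if (rss0 > 0) (rss0 - rss1) / rss0 else NA_real_
  }
  if (weak_warning && any(Fs < 10))
    warning("weak instrument: first-stage partial F below 10")
  structure(
    data.frame(exposure = colnames(X_end), estimate = est, se = se,
               statistic = stat, p = p, first_stage_F = Fs,
               first_stage_R2 = R2s, n = n, df = df, row.names = NULL),
    class = c("mr_result", "data.frame")
  )
}

qC_rank <- function(C) qr(C)$rank

#' Egger regression over per-variant summary statistics
#'
#' Weighted least squares of variant-outcome effects on variant-exposure
#' effects with an intercept, weights 1/se_outcome^2. Exposure effects are
#' oriented positive (flipping the corresponding outcome effect) before the
#' fit. The slope estimates the causal effect; a nonzero intercept indicates
#' net directional pleiotropy.
#'
#' @param beta_exposure Per-variant exposure effects.
#' @param beta_outcome Per-variant outcome effects.
#' @param se_outcome Standard errors of `beta_outcome`.
#' @return List of class `egger_result` with slope, slope_se, slope_p,
#'   intercept, intercept_se, pleiotropy_p, n_snps.
#' @export
egger_regression <- function(beta_exposure, beta_outcome, se_outcome) {
  k <- length(beta_exposure)
  if (k < 3) stop("insufficient instruments: Egger regression needs at least 3 variants")
  stopifnot(length(beta_outcome) == k, length(se_outcome) == k)
  flip <- sign(beta_exposure)
  flip[flip == 0] <- 1
  bx <- beta_exposure * flip
  by <- beta_outcome * flip
  w <- 1 / se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)$coefficients
  structure(
    list(slope = sm["bx", 1], slope_se = sm["bx", 2], slope_p = sm["bx", 4],
         intercept = sm["(Intercept)", 1], intercept_se = sm["(Intercept)", 2],
         pleiotropy_p = sm["(Intercept)", 4], n_snps = k),
    class = "egger_result"
  )
}

#' Analytic power for two-stage least-squares Mendelian randomization
#'
#' Power of the Wald test of the causal effect in a 2SLS analysis with a
#' continuous exposure and outcome, from the non-centrality parameter
#' `n * R2 * var_x * b^2 / var(structural residual)`. Vectorized over all
#' arguments.
#'
#' @param n Sample size.
#' @param r2_instrument Variance in the exposure explained by the
#'   instrument(s), in (0, 1).
#' @param causal_effect True causal effect (outcome units per exposure unit;
#'   SD units when both are standardized).
#' @param alpha Significance level.
#' @param var_exposure,var_outcome Variances of exposure and outcome
#'   (default 1, i.e. standardized).
#' @return Power (fraction), same length as the recycled arguments.
#' @export
mr_power <- function(n, r2_instrument, causal_effect, alpha = 0.05,
                     var_exposure = 1, var_outcome = 1) {
  stopifnot(all(r2_instrument > 0), all(r2_instrument < 1), all(n >= 10))
  vey <- var_outcome - causal_effect^2 * var_exposure
  if (any(vey <= 0))
    stop("causal effect too large for the stated outcome variance")
  ncp <- n * r2_instrument * var_exposure * causal_effect^2 / vey
  stats::pchisq(stats::qchisq(1 - alpha, df = 1), df = 1, ncp = ncp,
                lower.tail = FALSE)
}
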