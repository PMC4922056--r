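#' Covariate-adjusted ordinary least squares for a single predictor
#'
#' Fits `y ~ predictor + covariates` with an intercept and returns the
#' predictor coefficient with its standard error, t-statistic and two-sided
#' p-value. Categorical covariates (factors or character columns) are
#' expanded to indicator contrasts.
#'
#' @param y Numeric outcome vector.
#' @param predictor Numeric predictor vector.
#' @param covariates Optional data.frame or matrix of covariates.
#' @return An object of class `assoc_result`: a list with elements
#'   `estimate`, `se`, `statistic`, `p`, `n` and `df`.
#' @export
fit_ols <- function(y, predictor, covariates = NULL) {
  if (length(y) != length(predictor))
    stop("y and predictor must have equal length")
  X <- build_design(length(y), covariates)
  X <- cbind(`(Intercept)` = X[, 1], predictor = predictor, X[, -1, drop = FALSE])
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear design; offending columns: ", paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  df <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- if (df > 0) rss / df else NA_real_
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  est <- unname(fit$coefficients["predictor"])
  stat <- if (isTRUE(se > 0)) est / se else sign(est) * Inf
  p <- if (df > 0 && is.finite(stat)) 2 * stats::pt(-abs(stat), df) else NA_real_
  structure(
    list(estimate = est, se = se, statistic = stat, p = p, n = n, df = df,
         zero_residual = isTRUE(rss < 1e-12 * max(1, sum(y^2)))),
    class = "assoc_result"
  )
}

# Intercept-first design matrix; factors/characters expanded to contrasts.
build_design <- function(n, covariates = NULL) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  cov_df <- as.data.frame(covariates, stringsAsFactors = FALSE)
  keep <- rep(TRUE, length(cov_df))
  for (j in seq_along(cov_df)) {
    if (is.character(cov_df[[j]]) || is.logical(cov_df[[j]]))
      cov_df[[j]] <- factor(cov_df[[j]])
    # single-level factors carry no information and break model.matrix
    if (is.factor(cov_df[[j]]) && nlevels(droplevels(cov_df[[j]])) < 2)
      keep[j] <- FALSE
  }
  cov_df <- cov_df[keep]
  if (length(cov_df) == 0)
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  stats::model.matrix(~., data = cov_df)
}

#' Mass simple-regression scan with shared covariates
#'
#' Regresses every column of `Y` on `x`, adjusting for `covariates`, using
#' Frisch-Waugh-Lovell residualization. Numerically identical to per-column
#' [fit_ols] but orders of magnitude faster for matrix outcomes.
#'
#' @param Y Numeric matrix (samples x outcomes).
#' @param x Numeric predictor vector.
#' @param covariates Optional covariate data.frame/matrix.
#' @return data.frame with estimate, se, statistic, p, n, df per column of Y.
#' @export
fast_assoc <- function(Y, x, covariates = NULL) {
  Y <- as.matrix(Y)
  n <- length(x)
  stopifnot(nrow(Y) == n)
  C <- build_design(n, covariates)
  qC <- qr(C)
  xr <- qr.resid(qC, x)
  Yr <- qr.resid(qC, Y)
  sxx <- sum(xr^2)
  if (sxx < 1e-12) stop("predictor is collinear with covariates")
  b <- as.vector(crossprod(Yr, xr)) / sxx
  df <- n - qC$rank - 1
  rss <- pmax(colSums(Yr^2) - b^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  stat <- b / se
  p <- 2 * stats::pt(-abs(stat), df)
  data.frame(outcome = colnames(Y) %||% seq_len(ncol(Y)),
             estimate = b, se = se, statistic = stat, p = p,
             n = n, df = df, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
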