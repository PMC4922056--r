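# Multivariate-response partial least squares via NIPALS deflation.
# X and Y are centered; per component: iterate weight/score/loading until
# the X-score converges, then deflate X (and Y) by the score.
nipals_pls <- function(X, Y, ncomp, tol = 1e-10, maxit = 500) {
  n <- nrow(X)
  xbar <- colMeans(X); ybar <- colMeans(Y)
  Xc <- sweep(X, 2, xbar); Yc <- sweep(Y, 2, ybar)
  W <- matrix(0, ncol(X), ncomp)
  P <- matrix(0, ncol(X), ncomp)
  Q <- matrix(0, ncol(Y), ncomp)
  Tm <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    u <- Yc[, which.max(apply(Yc, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(maxit)) {
      w <- crossprod(Xc, u)
      w <- w / sqrt(sum(w^2))
      t <- Xc %*% w
      q <- crossprod(Yc, t) / sum(t^2)
      u <- Yc %*% q / sum(q^2)
      if (sum((t - t_old)^2) < tol * sum(t^2)) break
      t_old <- t
    }
    p <- crossprod(Xc, t) / sum(t^2)
    Xc <- Xc - t %*% t(p)
    Yc <- Yc - t %*% t(q)
    W[, a] <- w; P[, a] <- p; Q[, a] <- q; Tm[, a] <- t
  }
  # regression coefficients on the original (centered) X scale
  B <- W %*% solve(crossprod(P, W)) %*% t(Q)
  list(W = W, P = P, Q = Q, scores = Tm, coef = B,
       x_center = xbar, y_center = ybar)
}

pls_predict_raw <- function(fit, X, ncomp = NULL) {
  B <- if (is.null(ncomp)) fit$coef else {
    a <- seq_len(ncomp)
    fit$W[, a, drop = FALSE] %*%
      solve(crossprod(fit$P[, a, drop = FALSE], fit$W[, a, drop = FALSE])) %*%
      t(fit$Q[, a, drop = FALSE])
  }
  sweep(sweep(X, 2, fit$x_center) %*% B, 2, fit$y_center, `+`)
}

#' Train a partial-least-squares white-blood-cell predictor
#'
#' Fits a multivariate-response PLS model (NIPALS deflation) of the
#' neutrophil, lymphocyte and monocyte percentages on methylation features
#' plus age and gender, selecting the number of components by 5-fold
#' cross-validated RMSEP on a training split and reporting held-out
#' correlations on the remaining samples.
#'
#' @param features Sample x feature matrix (e.g. methylation betas).
#' @param responses data.frame/matrix of cell percentages (3 columns).
#' @param age,gender Covariate vectors, appended to the features.
#' @param max_components Largest component count tried.
#' @param folds Cross-validation folds.
#' @param test_fraction Held-out fraction (default one third).
#' @param max_features Cap on the most-variable features used.
#' @param seed Seed for the split and folds.
#' @return List of class `wbcc_model`: the PLS fit, `n_components`,
#'   `feature_ids`, `cv_rmsep` (per candidate count), `train_rmsep`,
#'   `test_correlation` and `test_rmsep` per response.
#' @export
train_wbcc <- function(features, responses, age, gender, max_components = 10,
                       folds = 5, test_fraction = 1/3, max_features = 5000,
                       seed = 1) {
  Y <- as.matrix(responses)
  if (anyNA(Y)) stop("training responses must be complete")
  n <- nrow(Y)
  if (n < 10) stop("insufficient data: need at least 10 training samples")
  set.seed(seed)
  vars <- apply(features, 2, stats::var)
  keep <- order(vars, decreasing = TRUE)[seq_len(min(max_features, ncol(features)))]
  keep <- sort(keep)
  X <- cbind(as.matrix(features)[, keep, drop = FALSE], age = age, gender = gender)
  test_idx <- sort(sample.int(n, round(test_fraction * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  Xtr <- X[train_idx, , drop = FALSE]; Ytr <- Y[train_idx, , drop = FALSE]
  max_components <- min(max_components, ncol(Xtr), length(train_idx) - 1L)

  fold_id <- sample(rep_len(seq_len(folds), length(train_idx)))
  sse <- matrix(0, max_components, ncol(Y))
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    fit <- nipals_pls(Xtr[!hold, , drop = FALSE], Ytr[!hold, , drop = FALSE],
                      min(max_components, sum(!hold) - 1L))
    for (a in seq_len(ncol(fit$W))) {
      pred <- pls_predict_raw(fit, Xtr[hold, , drop = FALSE], ncomp = a)
      sse[a, ] <- sse[a, ] + colSums((Ytr[hold, , drop = FALSE] - pred)^2)
    }
  }
  cv_rmsep <- sqrt(rowSums(sse) / (length(train_idx) * ncol(Y)))
  # smallest component count within 0.1 % of the best cross-validated RMSEP
  ncomp <- which(cv_rmsep <= min(cv_rmsep) * 1.001)[1]
  fit <- nipals_pls(Xtr, Ytr, ncomp)
  pred_tr <- pls_predict_raw(fit, Xtr)
  train_rmsep <- sqrt(colMeans((Ytr - pred_tr)^2))
  test_cor <- test_rmsep <- rep(NA_real_, ncol(Y))
  if (length(test_idx) > 2) {
    pred_te <- pls_predict_raw(fit, X[test_idx, , drop = FALSE])
    test_cor <- diag(stats::cor(Y[test_idx, , drop = FALSE], pred_te))
    test_rmsep <- sqrt(colMeans((Y[test_idx, , drop = FALSE] - pred_te)^2))
  }
  structure(
    list(fit = fit, n_components = ncomp, feature_ids = colnames(features)[keep],
         cv_rmsep = cv_rmsep, train_rmsep = train_rmsep,
         test_correlation = stats::setNames(test_cor, colnames(Y)),
         test_rmsep = test_rmsep, train_idx = train_idx, test_idx = test_idx),
    class = "wbcc_model"
  )
}

#' Predict white-blood-cell percentages from methylation
#'
#' @param model A `wbcc_model`.
#' @param features Sample x feature matrix; must contain the training
#'   feature ids.
#' @param age,gender Covariates.
#' @return Matrix of predicted percentages, clipped at 0 from below.
#' @export
predict_wbcc <- function(model, features, age, gender) {
  missing_ids <- setdiff(model$feature_ids, colnames(features))
  if (length(missing_ids) > 0)
    stop("feature mismatch; missing: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) " ...")
  X <- cbind(as.matrix(features)[, model$feature_ids, drop = FALSE],
             age = age, gender = gender)
  pmax(pls_predict_raw(model$fit, X), 0)
}
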