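# Independent closed-form oracles, kept deliberately separate from the
# package implementations: explicit normal equations and matrix algebra.

ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  e <- y - X %*% b
  df <- length(y) - ncol(X)
  V <- as.numeric(crossprod(e) / df) * solve(XtX)
  list(coef = as.vector(b), se = unname(sqrt(diag(V))), df = df)
}

# closed-form instrumental variables: b = (X'Pz X)^{-1} X'Pz y,
# V = s2 (X'Pz X)^{-1} with structural residuals
iv_oracle <- function(y, X, Z) {
  Pz <- Z %*% solve(crossprod(Z)) %*% t(Z)
  A <- t(X) %*% Pz %*% X
  b <- solve(A, t(X) %*% Pz %*% y)
  e <- y - X %*% b
  s2 <- sum(e^2) / (length(y) - ncol(X))
  list(coef = as.vector(b), se = unname(sqrt(diag(s2 * solve(A)))))
}

wls_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  b <- solve(XtWX, t(X) %*% (w * y))
  e <- y - X %*% b
  s2 <- sum(w * e^2) / (length(y) - 2)
  V <- s2 * solve(XtWX)
  list(intercept = unname(b[1]), slope = unname(b[2]), se = unname(sqrt(diag(V))))
}

# small multi-cohort study for integration-level tests
tiny_study <- function(seed = 11, n_per_cohort = c(250, 300, 250), n_cpgs = 400,
                       preset = "full-topology", ...) {
  args <- list(preset = preset, seed = seed, n_per_cohort = n_per_cohort,
               n_cpgs = n_cpgs, n_forward = 9, n_reverse = 6,
               n_meqtl_direct = 3, n_pleiotropic = 3, n_confounded = 12)
  dots <- list(...)
  args[names(dots)] <- dots
  simulate_study(do.call(default_sim_config, args))
}
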