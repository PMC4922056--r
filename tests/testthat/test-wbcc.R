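test_that("noiseless low-rank responses are recovered with few components", {
  set.seed(100)
  n <- 300; p <- 40
  latent <- matrix(rnorm(n * 2), n, 2)  # two latent directions
  X <- latent %*% matrix(rnorm(2 * p), 2, p) +
    matrix(rnorm(n * p, 0, 1e-6), n, p)
  Y <- latent %*% matrix(c(1, 0.5, -0.3, 0.2, 1, 0.8), 2, 3)
  colnames(Y) <- c("neut", "lymph", "mono")
  fit <- train_wbcc(X, Y, age = rnorm(n), gender = rbinom(n, 1, 0.5),
                    max_components = 6, seed = 1)
  # age and gender enter as two further feature directions, so the CV pick
  # must not exceed the latent dimension (2) plus the covariate columns (2)
  expect_lte(fit$n_components, 4)
  expect_true(all(fit$test_correlation > 0.99))
})

test_that("pure-noise responses have held-out correlation near zero", {
  set.seed(101)
  n <- 240; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(abs(rnorm(n * 3, 50, 5)), n, 3)
  colnames(Y) <- c("neut", "lymph", "mono")
  fit <- train_wbcc(X, Y, age = rnorm(n), gender = rbinom(n, 1, 0.5),
                    max_components = 5, seed = 2)
  n_test <- length(fit$test_idx)
  expect_true(all(abs(fit$test_correlation) < 3 / sqrt(n_test)))
})

test_that("a one-component fit equals the explicit NIPALS deflation oracle", {
  set.seed(102)
  n <- 50; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * 2), n, 2)
  fit <- lipidmr:::nipals_pls(X, Y, ncomp = 1)
  # hand-rolled single component: power iteration on the centered matrices
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  u <- Yc[, which.max(apply(Yc, 2, var))]
  for (it in 1:200) {
    w <- crossprod(Xc, u); w <- w / sqrt(sum(w^2))
    t <- Xc %*% w
    q <- crossprod(Yc, t) / sum(t^2)
    u <- Yc %*% q / sum(q^2)
  }
  B_hand <- w %*% solve(crossprod(crossprod(Xc, t) / sum(t^2), w)) %*% t(q)
  expect_equal(abs(fit$coef), abs(B_hand), tolerance = 1e-4,
               ignore_attr = TRUE)
  pred <- lipidmr:::pls_predict_raw(fit, X)
  B <- fit$coef
  expect_equal(pred, sweep(Xc %*% B, 2, colMeans(Y), `+`),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("prediction validates features, clips at zero and is consistent", {
  set.seed(103)
  n <- 120; p <- 20
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  Y <- X[, 1:3] * 5 + 40 + matrix(rnorm(n * 3), n, 3)
  colnames(Y) <- c("neut", "lymph", "mono")
  age <- rnorm(n); gender <- rbinom(n, 1, 0.5)
  fit <- train_wbcc(X, Y, age, gender, max_components = 5, seed = 3)
  pred <- predict_wbcc(fit, X, age, gender)
  expect_true(all(pred >= 0))
  # in-sample RMSEP on the training rows matches the training report
  tr <- fit$train_idx
  rmsep <- sqrt(colMeans((Y[tr, ] - pmax(
    lipidmr:::pls_predict_raw(fit$fit,
      cbind(X[tr, fit$feature_ids], age = age[tr], gender = gender[tr])), -Inf))^2))
  expect_equal(unname(rmsep), unname(fit$train_rmsep), tolerance = 1e-10)
  expect_error(predict_wbcc(fit, X[, -1], age, gender), "feature mismatch")
  expect_error(train_wbcc(X[1:5, ], Y[1:5, ], age[1:5], gender[1:5]),
               "insufficient data")
})

test_that("refitting on affinely rescaled features leaves predictions stable", {
  set.seed(104)
  n <- 200; p <- 15
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  Y <- X[, 1:2] %*% rbind(c(3, 1, 0), c(0, 2, 4)) + 30 +
    matrix(rnorm(n * 3, 0, 0.5), n, 3)
  colnames(Y) <- c("neut", "lymph", "mono")
  age <- rnorm(n); gender <- rbinom(n, 1, 0.5)
  f1 <- train_wbcc(X, Y, age, gender, max_components = 4, seed = 5)
  X2 <- X * 2 + 1
  f2 <- train_wbcc(X2, Y, age, gender, max_components = 4, seed = 5)
  p1 <- predict_wbcc(f1, X, age, gender)
  p2 <- predict_wbcc(f2, X2, age, gender)
  expect_equal(p1, p2, tolerance = 0.05)
})
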