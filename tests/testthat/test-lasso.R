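test_that("full shrinkage returns an intercept-only fit", {
  set.seed(1)
  z <- matrix(rnorm(200), 50)
  colnames(z) <- paste0("z", 1:4)
  y <- rnorm(50, mean = 3)
  fit <- lasso_linear(z, y, z_new = z[1:5, ], lambda = Inf)
  expect_identical(fit$selected, character(0))
  expect_equal(fit$fitted_new, rep(mean(y), 5), tolerance = 1e-12)
})

test_that("on an orthonormal design the solution is the soft threshold", {
  X <- orthonormal_design(n = 64, p = 8)
  set.seed(6)
  beta <- c(2, -1.5, 0.8, 0.3, 0.1, 0, 0, 0)
  y <- drop(X %*% beta) + rnorm(64, 0, 0.2)
  lam <- 0.5
  fit <- lasso_linear(X, y, lambda = lam)
  b_ols <- drop(crossprod(X, y - mean(y))) / nrow(X)
  expect_equal(unname(fit$coef_lasso[colnames(X)]),
               unname(soft_threshold(b_ols, lam)), tolerance = 1e-5)
  expect_identical(sort(fit$selected),
                   sort(colnames(X)[abs(b_ols) > lam]))
})

test_that("the single-column closed form matches the soft threshold too", {
  set.seed(9)
  x <- matrix(rnorm(400), dimnames = list(NULL, "z1"))
  y <- 0.8 * x[, 1] + rnorm(400, 0, 0.5)
  lam <- 0.3
  fit <- lasso_linear(x, y, lambda = lam)
  n <- 400
  xs <- (x[, 1] - mean(x[, 1])) / sqrt(mean((x[, 1] - mean(x[, 1]))^2))
  b_std <- mean(xs * (y - mean(y)))
  expect_equal(unname(fit$coef_lasso["z1"]),
               soft_threshold(b_std, lam) /
                 sqrt(mean((x[, 1] - mean(x[, 1]))^2)),
               tolerance = 1e-10)
})

test_that("zero penalty reduces to OLS on all columns", {
  set.seed(2)
  z <- matrix(rnorm(300), 100); colnames(z) <- paste0("z", 1:3)
  y <- drop(z %*% c(1, -1, 2)) + rnorm(100)
  fit <- lasso_linear(z, y, lambda = 0)
  b <- ols_oracle(cbind(1, z), y)
  expect_equal(unname(fit$coef_post), unname(b), tolerance = 1e-10)
})

test_that("strong sparse signals are screened in with high frequency", {
  hits <- 0L
  n_seeds <- 30L
  for (sd in seq_len(n_seeds)) {
    set.seed(1000 + sd)
    n <- 1000; p <- 200
    z <- matrix(rnorm(n * p), n); colnames(z) <- paste0("z", seq_len(p))
    y <- drop(z[, 1:5] %*% rep(1, 5)) + rnorm(n)
    fit <- lasso_linear(z, y, lambda = "plugin")
    if (all(paste0("z", 1:5) %in% fit$selected)) hits <- hits + 1L
  }
  expect_gt(hits / n_seeds, 0.95)
})

test_that("post-LASSO predictions beat penalized predictions on the support", {
  set.seed(12)
  n <- 400; p <- 50
  z <- matrix(rnorm(n * p), n); colnames(z) <- paste0("z", seq_len(p))
  ytrue <- drop(z[, 1:3] %*% c(2, -2, 1.5))
  y <- ytrue + rnorm(n)
  znew <- matrix(rnorm(50 * p), 50); colnames(znew) <- colnames(z)
  ynew <- drop(znew[, 1:3] %*% c(2, -2, 1.5))
  f_post <- lasso_linear(z, y, z_new = znew, lambda = "plugin", post = TRUE)
  f_pen <- lasso_linear(z, y, z_new = znew, lambda = "plugin", post = FALSE)
  expect_lt(mean((f_post$fitted_new - ynew)^2),
            mean((f_pen$fitted_new - ynew)^2))
})

test_that("logistic full shrinkage predicts the training prevalence", {
  set.seed(3)
  z <- matrix(rnorm(400), 100); colnames(z) <- paste0("z", 1:4)
  y <- rbinom(100, 1, 0.3)
  fit <- lasso_logit(z, y, z_new = z[1:4, ], lambda = Inf)
  expect_identical(fit$selected, character(0))
  expect_equal(plogis(fit$g_new), rep(mean(y), 4), tolerance = 1e-8)
})

test_that("penalized logit improves on the intercept-only deviance", {
  set.seed(4)
  n <- 2000; p <- 100
  z <- matrix(rnorm(n * p), n); colnames(z) <- paste0("z", seq_len(p))
  y <- rbinom(n, 1, plogis(drop(z[, 1:5] %*% rep(0.8, 5))))
  fit <- lasso_logit(z, y, z_new = z, lambda = "plugin")
  eta <- fit$g_new
  dev <- -2 * sum(y * log(plogis(eta)) + (1 - y) * log(1 - plogis(eta)))
  p0 <- mean(y)
  dev0 <- -2 * sum(y * log(p0) + (1 - y) * log(1 - p0))
  expect_lt(dev, dev0)
  expect_gt(length(fit$selected), 0)
})

test_that("coefficient l1 norm shrinks as the logit penalty grows", {
  set.seed(5)
  n <- 500; p <- 30
  z <- matrix(rnorm(n * p), n); colnames(z) <- paste0("z", seq_len(p))
  y <- rbinom(n, 1, plogis(drop(z[, 1:3] %*% c(1, -1, 1))))
  lams <- c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2)
  norms <- vapply(lams, function(l) {
    fit <- lasso_logit(z, y, lambda = l, post = FALSE)
    sum(abs(fit$coef_lasso[colnames(z)]))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("single-class training folds are rejected with actionable advice", {
  z <- matrix(rnorm(40), 20)
  expect_error(lasso_logit(z, rep(1, 20)), "stratified")
})

test_that("unpenalized treatment columns always stay in the logit model", {
  set.seed(8)
  n <- 800; p <- 40
  z <- matrix(rnorm(n * p), n); colnames(z) <- paste0("z", seq_len(p))
  d <- matrix(rnorm(n), dimnames = list(NULL, "d"))
  y <- rbinom(n, 1, plogis(0.6 * d[, 1] + z[, 1]))
  fit <- lasso_logit(z, y, unpen = d, lambda = 0.2)  # heavy penalty on z
  expect_true(is.finite(fit$beta_unpen["d"]))
  expect_gt(abs(fit$beta_unpen["d"]), 0.2)
})
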