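# Independent brute-force oracles used across the suite. These deliberately
# use the most literal formulation of each computation (explicit normal
# equations, per-point weighted means, enumeration) so they share no code
# with the implementation they check.

# textbook OLS via explicit normal equations
ols_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

soft_threshold <- function(b, lam) sign(b) * pmax(abs(b) - lam, 0)

# per-grid-point Epanechnikov weighted mean, written as an explicit loop
kernel_mean_oracle <- function(age, haz, grid, h) {
  out <- numeric(length(grid))
  for (i in seq_along(grid)) {
    num <- 0; den <- 0
    for (j in seq_along(age)) {
      u <- (age[j] - grid[i]) / h
      if (abs(u) < 1) {
        w <- 0.75 * (1 - u^2)
        num <- num + w * haz[j]
        den <- den + w
      }
    }
    out[i] <- if (den > 0) num / den else NA_real_
  }
  out
}

# small data set with two treatments, a few controls and known coefficients
make_linear_fixture <- function(n = 200, beta = c(-0.5, 0.25),
                                phi = c(1, -1, 0.5), sd = 0, seed = 99) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(phi)), n,
              dimnames = list(NULL, paste0("x", seq_along(phi))))
  D <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("d1", "d2")))
  y <- drop(D %*% beta) + drop(X %*% phi) + rnorm(n, 0, sd)
  data.frame(y = y, D, X)
}

# orthonormal design with columns orthogonal to the intercept and
# (1/n) X'X = I, so the penalized solution has a closed form
orthonormal_design <- function(n = 64, p = 8, seed = 5) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n))))[, -1, drop = FALSE]
  X <- Q * sqrt(n)
  colnames(X) <- paste0("q", seq_len(p))
  X
}
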