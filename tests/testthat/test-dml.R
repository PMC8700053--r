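test_that("resample aggregation implements the dispersion-augmented rule", {
  # R = 1: identity
  one <- aggregate_resamples(matrix(1.7, 1, 1), list(matrix(0.3, 1, 1)))
  expect_equal(one$estimate, 1.7, ignore_attr = TRUE)
  expect_equal(one$vcov[1, 1], 0.3)
  # hand-computed: estimates (1, 3), variances (0.5, 0.5)
  two <- aggregate_resamples(c(1, 3), c(0.5, 0.5))
  expect_equal(two$estimate, 2, ignore_attr = TRUE)
  expect_equal(two$vcov[1, 1], 1.5)
  # identical estimates: dispersion term vanishes
  same <- aggregate_resamples(c(2, 2, 2), c(0.1, 0.2, 0.3))
  expect_equal(same$vcov[1, 1], 0.2)
})

test_that("aggregated variance never falls below the mean within-split variance", {
  set.seed(30)
  for (i in 1:20) {
    R <- sample(2:6, 1)
    est <- rnorm(R)
    V <- runif(R, 0.01, 1)
    agg <- aggregate_resamples(est, V)
    expect_gte(agg$vcov[1, 1], mean(V) - 1e-12)
  }
})

test_that("zero penalty and a single split reproduce full-sample OLS (FWL)", {
  set.seed(14)
  n <- 300
  z <- matrix(rnorm(n * 4), n); colnames(z) <- paste0("z", 1:4)
  d <- cbind(d1 = rnorm(n) + z[, 1], d2 = rnorm(n) - z[, 2])
  y <- drop(d %*% c(0.7, -0.4)) + drop(z %*% c(1, 1, -1, 0.5)) + rnorm(n)
  plan <- make_folds(n, K = 1, R = 1, seed = 3)
  dml <- crossfit_plm(y, d, z, plan, lambda = 0)
  b <- ols_oracle(cbind(1, d, z), y)
  expect_equal(dml$coefficients$estimate, unname(b[2:3]), tolerance = 1e-10)
})

test_that("with no controls the engine reduces to OLS of Y on D", {
  set.seed(15)
  n <- 250
  d <- cbind(d1 = rnorm(n))
  y <- 0.5 * d[, 1] + rnorm(n)
  plan <- make_folds(n, K = 1, R = 1, seed = 1)
  dml <- crossfit_plm(y, d, NULL, plan)
  b <- ols_oracle(cbind(1, d), y)
  expect_equal(dml$coefficients$estimate, unname(b[2]), tolerance = 1e-10)
})

test_that("estimates are exactly invariant to fold relabeling", {
  set.seed(16)
  n <- 240
  z <- matrix(rnorm(n * 30), n); colnames(z) <- paste0("z", 1:30)
  d <- cbind(d1 = rnorm(n) + z[, 1])
  y <- 0.4 * d[, 1] + z[, 1] + rnorm(n)
  plan <- make_folds(n, K = 4, R = 2, seed = 5)
  ref <- crossfit_plm(y, d, z, plan, lambda = "cv")
  perm <- plan
  relab <- c(3L, 1L, 4L, 2L)
  perm$assign <- matrix(relab[plan$assign], n, 2)
  got <- crossfit_plm(y, d, z, perm, lambda = "cv")
  expect_identical(got$coefficients$estimate, ref$coefficients$estimate)
  expect_identical(got$coefficients$std_error, ref$coefficients$std_error)
})

test_that("an unidentified (constant) treatment is reported as an error", {
  set.seed(17)
  n <- 120
  z <- matrix(rnorm(n * 5), n); colnames(z) <- paste0("z", 1:5)
  d <- cbind(d1 = rep(1, n))
  expect_error(crossfit_plm(rnorm(n), d, z, make_folds(n, 3, 1, 1)),
               "not identified")
})

test_that("cross-fit logit with no controls equals the plain logit", {
  set.seed(18)
  n <- 800
  d <- cbind(d = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.2 + 0.6 * d[, 1]))
  plan <- make_folds(n, K = 1, R = 1, seed = 2, stratify = y)
  dml <- crossfit_logit(y, d, NULL, plan)
  ref <- glm(y ~ d[, 1], family = binomial)
  expect_equal(dml$coefficients$estimate, unname(coef(ref)[2]),
               tolerance = 1e-6)
  adhoc <- fit_logit_adhoc(data.frame(y = y, d = d[, 1]),
                           adhoc_spec("y", "d", character(0),
                                      family = "logit"))
  expect_equal(dml$coefficients$odds_ratio, adhoc$coefficients$odds_ratio,
               tolerance = 1e-6)
})

test_that("cross-fit logit recovers a known effect with controls", {
  set.seed(19)
  n <- 3000; p <- 40
  z <- matrix(rnorm(n * p), n); colnames(z) <- paste0("z", seq_len(p))
  d <- cbind(d = rnorm(n) + 0.8 * z[, 1])
  y <- rbinom(n, 1, plogis(0.5 * d[, 1] + z[, 1] - 0.5 * z[, 2]))
  plan <- make_folds(n, K = 4, R = 1, seed = 4, stratify = y)
  dml <- crossfit_logit(y, d, z, plan, lambda = "plugin")
  est <- dml$coefficients$estimate
  se <- dml$coefficients$std_error
  expect_lt(abs(est - 0.5), 3.5 * se)
})

test_that("logit CIs cover a small education odds ratio", {
  nrep <- 100
  covered <- integer(nrep)
  for (i in seq_len(nrep)) {
    sim <- simulate_ecd(sim_scenario("logit_alt", seed = 50000 + i))
    d <- sim$data
    plan <- make_folds(nrow(d), K = 5, R = 1, seed = 60000 + i,
                       stratify = d$y_ontrack)
    dm <- crossfit_logit(d$y_ontrack,
                         as.matrix(d[, c("haz", "edu_years")]),
                         as.matrix(d[, sim$z_cols]), plan,
                         lambda = "plugin")
    co <- dm$coefficients[dm$coefficients$term == "edu_years", ]
    covered[i] <- as.integer(co$conf_low <= log(1.03) &
                               log(1.03) <= co$conf_high)
  }
  expect_gte(sum(covered), 90L)
})

test_that("pure-noise controls are rarely selected on the default scenario", {
  sel_reps <- 0L; total_reps <- 0L
  for (sd in 1:3) {
    sim <- simulate_ecd(sim_scenario("confounded_plm", n = 1200, p = 80,
                                     s = 5, seed = 700 + sd))
    d <- sim$data
    set.seed(sd)
    Z <- cbind(as.matrix(d[, sim$z_cols]), pure_noise = rnorm(nrow(d)))
    plan <- make_folds(nrow(d), K = 4, R = 5, seed = sd)
    dml <- crossfit_plm(d$y_ecdi, as.matrix(d[, c("haz", "edu_years")]), Z,
                        plan, lambda = "plugin")
    for (r in 1:plan$R) {
      total_reps <- total_reps + 1L
      hit <- any(vapply(dml$selection$selected,
                        function(s) "pure_noise" %in% s[[r]], logical(1)))
      if (hit) sel_reps <- sel_reps + 1L
    }
  }
  expect_lt(sel_reps / total_reps, 0.2)
})

test_that("bookkeeping: K folds and R repetitions give K*R fits per nuisance", {
  set.seed(20)
  n <- 150
  z <- matrix(rnorm(n * 10), n); colnames(z) <- paste0("z", 1:10)
  d <- cbind(d1 = rnorm(n), d2 = rnorm(n))
  y <- rnorm(n)
  dml <- crossfit_plm(y, d, z, make_folds(n, K = 5, R = 3, seed = 1),
                      lambda = "plugin")
  expect_identical(unname(dml$n_lasso_fits), rep(15L, 3))
  expect_identical(names(dml$n_lasso_fits), c("Y", "d1", "d2"))
  expect_identical(dim(dml$selection$count), c(3L, 3L))
  expect_identical(nrow(dml$per_rep$estimates), 3L)
})
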