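test_that("the control table has exactly p columns and the named ad-hoc subset", {
  sim <- simulate_ecd(sim_config(n = 120, p = 451, s = 10, seed = 2))
  expect_length(sim$z_cols, 451)
  expect_true(all(sim$x_cols %in% sim$z_cols))
  expect_length(sim$x_cols, 16)
  expect_true(any(grepl("^rural_x_", sim$z_cols)))
  expect_true(any(grepl("^asset_", sim$z_cols)))
  # too-small p for the requested sparsity is caught up front
  expect_error(simulate_ecd(sim_config(n = 50, p = 40, s = 10, seed = 1)),
               "too small")
})

test_that("generation is fully deterministic in the config seed", {
  cfg <- sim_config(n = 300, p = 60, s = 5, seed = 11)
  a <- simulate_ecd(cfg)
  b <- simulate_ecd(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_ecd(sim_config(n = 300, p = 60, s = 5, seed = 12))
  expect_false(identical(a$data$y_ecdi, c2$data$y_ecdi))
})

test_that("population structure matches the survey it emulates", {
  sim <- simulate_ecd(sim_config(n = 10000, p = 60, s = 5, seed = 21))
  d <- sim$data
  # rural share 0.69 within 2 binomial SEs
  expect_lt(abs(mean(d$rural) - 0.69), 2 * sqrt(0.69 * 0.31 / 10000))
  # education split by area (integer years in 0..18)
  expect_true(all(d$edu_years >= 0 & d$edu_years <= 18))
  expect_lt(abs(mean(d$edu_years[d$rural == 0]) - 8.32), 0.5)
  expect_gt(mean(d$edu_years[d$rural == 0]) -
              mean(d$edu_years[d$rural == 1]), 3)
  # mean HAZ of the older cohort is calibrated to -1.87
  expect_lt(abs(mean(d$haz[d$age_months >= 36]) + 1.87), 0.05)
  # stunting flag consistent with the threshold rule
  expect_identical(d$stunted, as.integer(d$haz <= -2))
})

test_that("zero confounding decouples education from the outcome signal", {
  sim <- simulate_ecd(sim_config(n = 10000, p = 60, s = 5,
                                 confounding = 0, seed = 31))
  expect_lt(abs(cor(sim$data$edu_years, sim$data$f_z)), 0.05)
})

test_that("oracle regressions on the true supports recover the coefficients", {
  cfg <- sim_config(n = 10000, p = 100, s = 8, d1_type = "haz",
                    edu_integer = FALSE, seed = 41)
  sim <- simulate_ecd(cfg)
  d <- sim$data; tr <- sim$truth
  within_3se <- function(fit, theta) {
    sm <- summary(fit)$coefficients
    est <- sm[names(theta), 1]; se <- sm[names(theta), 2]
    all(abs(est - theta) < 3 * se)
  }
  # f: outcome equation given both treatments
  f_fit <- lm(stats::reformulate(c("haz", "edu_years", names(tr$theta_f)),
                                 "y_ecdi"), data = d)
  expect_true(within_3se(f_fit, tr$theta_f))
  # g: HAZ equation; the age curve is quadratic, so age + age_sq absorb it
  g_cols <- unique(c(names(tr$theta_g_shared), names(tr$theta_g_own)))
  g_theta <- (c(tr$theta_g_shared, rep(0, length(tr$theta_g_own))) +
                c(rep(0, length(tr$theta_g_shared)), tr$theta_g_own))
  names(g_theta) <- c(names(tr$theta_g_shared), names(tr$theta_g_own))
  g_fit <- lm(stats::reformulate(c("age_months", "age_sq", "rural", g_cols),
                                 "haz"), data = d)
  expect_true(within_3se(g_fit, g_theta))
  # h: education equation
  h_cols <- c(names(tr$theta_h_shared), names(tr$theta_h_own))
  h_theta <- stats::setNames(c(tr$theta_h_shared, tr$theta_h_own), h_cols)
  h_fit <- lm(stats::reformulate(c("rural", h_cols), "edu_latent"), data = d)
  expect_true(within_3se(h_fit, h_theta))
})

test_that("naive OLS bias matches the closed-form omitted-variable formula", {
  cfg <- sim_scenario("confounded_plm", edu_integer = FALSE)
  nrep <- 30
  est <- matrix(NA_real_, nrep, 2)
  biases <- matrix(NA_real_, nrep, 2)  # supports are redrawn per seed
  for (i in seq_len(nrep)) {
    cfg_i <- sim_scenario("confounded_plm", edu_integer = FALSE,
                          seed = 5000 + i)
    sim <- simulate_ecd(cfg_i)
    biases[i, ] <- analytic_naive_bias(sim$truth, cfg_i)
    sp <- adhoc_spec("y_ecdi", c("haz", "edu_latent"), sim$x_cols)
    est[i, ] <- fit_linear_adhoc(sim$data, sp)$coefficients$estimate
  }
  truth <- c(cfg$beta1, cfg$beta2)
  observed_bias <- colMeans(est) - truth
  predicted_bias <- colMeans(biases)
  mc_se <- apply(est, 2, sd) / sqrt(nrep)
  expect_lt(abs(observed_bias[1] - predicted_bias[1]), 4 * mc_se[1])
  expect_lt(abs(observed_bias[2] - predicted_bias[2]), 4 * mc_se[2])
  # and the bias is large relative to Monte-Carlo noise (the scenario has
  # power for the naive-vs-DML comparison)
  expect_gt(abs(observed_bias[2]), 5 * mc_se[2])
})

test_that("item intercepts are calibrated to the domain share targets", {
  cfg <- sim_config(n = 4000, p = 60, s = 5, seed = 51)
  set.seed(51)
  latent <- rnorm(4000)
  it <- gen_items(latent, cfg)
  sc <- score_ecd(it$items)
  shares <- colMeans(sc[, paste0("ontrack_", names(ecd_domains))])
  expect_lt(max(abs(shares - cfg$item_targets[names(ecd_domains)])), 0.03)
})

test_that("item discrimination controls the latent-score correlation", {
  set.seed(61)
  latent <- rnorm(4000)
  cors <- vapply(c(0, 0.7, 2), function(b) {
    cfg <- sim_config(n = 4000, p = 60, s = 5, item_slope = b, seed = 61)
    it <- gen_items(latent, cfg)
    cor(rowSums(it$items), latent)
  }, numeric(1))
  expect_lt(abs(cors[1]), 0.05)     # no signal
  expect_true(all(diff(cors) > 0))  # monotone in the slope
})

test_that("the HAZ age curve falls to 35 months then recovers", {
  cfg <- sim_config(n = 200, p = 60, s = 5, seed = 71)
  set.seed(71)
  prof <- gen_age_profile(5000, cfg, noise_sd = 0)
  curve <- tapply(prof$haz, prof$age_months, unique)
  ages <- as.integer(names(curve))
  expect_true(all(diff(curve[ages <= 35]) < 0))
  expect_true(all(diff(curve[ages >= 36]) >= 0))
  # noiseless values sit exactly on the curve: one value per age
  expect_true(all(lengths(tapply(prof$haz, prof$age_months, unique)) == 1))
  # rural offset shifts levels by the configured gap
  set.seed(72)
  pr <- gen_age_profile(20000, cfg, rural_offset = TRUE, noise_sd = 0.3)
  gap <- mean(pr$haz[pr$rural == 0]) - mean(pr$haz[pr$rural == 1])
  expect_lt(abs(gap - cfg$haz_rural_gap), 0.05)
})

test_that("the mediation regime adds an education-to-HAZ channel", {
  base <- sim_config(n = 6000, p = 60, s = 5, regime = "mediation",
                     channel = 0.15, seed = 81)
  none <- sim_config(n = 6000, p = 60, s = 5, regime = "mediation",
                     channel = 0, seed = 81)
  a <- simulate_ecd(base)$data
  b <- simulate_ecd(none)$data
  # same seed, only the channel differs: HAZ shifts with education
  slope_a <- coef(lm(haz ~ edu_years + age_months + age_sq + rural,
                     data = a))["edu_years"]
  slope_b <- coef(lm(haz ~ edu_years + age_months + age_sq + rural,
                     data = b))["edu_years"]
  expect_gt(slope_a - slope_b, 0.10)
})
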