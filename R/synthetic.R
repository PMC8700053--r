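# MICS-like synthetic child-level data with known causal structure.
# Everything is driven by a single config + seed: a high-dimensional control
# table (asset indicators, categorical dummies, rural interactions), two
# confounded treatments (child HAZ / stunting and mother's education), a
# partially linear continuous development score, a logistic on-track
# indicator, item-level ECD responses calibrated to target domain shares,
# and a quadratic growth-faltering age profile of HAZ.

#' Configuration for the synthetic MICS-like generator
#'
#' Defaults emulate the Nigeria survey the analysis is designed for:
#' ~10,000 children, 451 candidate controls, 69% rural, six regions,
#' mean maternal education 3.27 years rural / 8.32 urban, a 36--59-month
#' mean HAZ of -1.87, domain on-track shares (0.30, 0.92, 0.79, 0.72) and
#' treatment effects of the magnitude the method is meant to detect
#' (about -0.18 SD of the development score per stunting episode, +0.02 SD
#' per year of maternal education, odds ratios 0.711 and 1.03 for the
#' binary on-track outcome).
#'
#' @param n number of children.
#' @param p number of expanded control columns (exactly).
#' @param s sparsity: number of support columns per nuisance function.
#' @param d1_type `"stunted"` (binary stature treatment in the structural
#'   outcome) or `"haz"` (continuous).
#' @param beta1 effect of the stature treatment on the continuous score;
#'   default -0.18 for `"stunted"`, -0.2 for `"haz"`.
#' @param beta2 effect per year of maternal education on the continuous
#'   score.
#' @param or1,or2 odds ratios of the stature treatment and of one education
#'   year on the binary on-track outcome.
#' @param confounding scale of the shared (confounding) components of the
#'   treatment equations; 0 = unconfounded.
#' @param regime `"plm"` (treatments depend on controls only) or
#'   `"mediation"` (HAZ additionally depends on education with coefficient
#'   `channel`, the education-to-nutrition channel).
#' @param channel HAZ gain per education year in the mediation regime.
#' @param rural_share population share of rural children.
#' @param region_probs region membership probabilities.
#' @param edu_rural_mean,edu_urban_mean,edu_sd maternal education location
#'   by area and idiosyncratic SD (years).
#' @param edu_integer round/censor education to whole years in 0--18 (the
#'   realistic zero-inflated distribution); `FALSE` keeps the continuous
#'   latent scale (exact partially-linear case).
#' @param haz_36_59_mean calibration target for mean HAZ among 36--59-month
#'   olds.
#' @param haz_rural_gap urban-minus-rural HAZ gap (SD units).
#' @param haz_noise_sd idiosyncratic HAZ noise SD.
#' @param sigma_y noise SD of the continuous development score.
#' @param p_ontrack target prevalence of the binary on-track outcome.
#' @param item_targets named domain on-track share targets for item
#'   calibration.
#' @param item_slope discrimination of the items on the latent score.
#' @param seed integer seed; the dataset is a deterministic function of the
#'   config.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n = 10000L, p = 451L, s = 10L,
                       d1_type = c("stunted", "haz"),
                       beta1 = NULL, beta2 = 0.02,
                       or1 = 0.711, or2 = 1.03,
                       confounding = 1, regime = c("plm", "mediation"),
                       channel = 0.01,
                       rural_share = 0.69,
                       region_probs = c(0.17, 0.22, 0.38, 0.05, 0.08, 0.10),
                       edu_rural_mean = 3.27, edu_urban_mean = 8.32,
                       edu_sd = 2.2, edu_integer = TRUE,
                       haz_36_59_mean = -1.87, haz_rural_gap = 0.77,
                       haz_noise_sd = 0.9,
                       sigma_y = 0.85, p_ontrack = 0.63,
                       item_targets = c(literacy = 0.30, physical = 0.92,
                                        learning = 0.79,
                                        socioemotional = 0.72),
                       item_slope = 1, seed = 1L) {
  d1_type <- match.arg(d1_type)
  regime <- match.arg(regime)
  if (is.null(beta1)) beta1 <- if (d1_type == "stunted") -0.18 else -0.2
  stopifnot(s >= 1, s <= p, rural_share > 0, rural_share < 1,
            abs(sum(region_probs) - 1) < 1e-8,
            all(item_targets > 0), all(item_targets < 1))
  structure(list(
    n = as.integer(n), p = as.integer(p), s = as.integer(s),
    d1_type = d1_type, beta1 = beta1, beta2 = beta2, or1 = or1, or2 = or2,
    confounding = confounding, regime = regime, channel = channel,
    rural_share = rural_share, region_probs = region_probs,
    edu_rural_mean = edu_rural_mean, edu_urban_mean = edu_urban_mean,
    edu_sd = edu_sd, edu_integer = isTRUE(edu_integer),
    haz_36_59_mean = haz_36_59_mean, haz_rural_gap = haz_rural_gap,
    haz_noise_sd = haz_noise_sd,
    haz_bottom = -2.45, haz_rise = 2.15, haz_vertex = 35.5,
    sigma_y = sigma_y, p_ontrack = p_ontrack,
    item_targets = item_targets, item_slope = item_slope,
    seed = as.integer(seed)), class = "sim_config")
}

#' Named reduced scenarios used in simulation studies
#'
#' `"confounded_plm"` is the default Monte-Carlo scenario for parameter
#' recovery: n = 4000, p = 200, s = 10, continuous HAZ treatment with
#' (beta1, beta2) = (-0.2, 0.02) and strongly confounded treatments.
#' `"logit_null"` is a reduced binary-outcome scenario with a null education
#' effect (or2 = 1) for size checks; `"logit_alt"` the same with
#' or2 = 1.03.
#'
#' @param which scenario name.
#' @param ... overrides passed to [sim_config()] (e.g. `n`, `seed`).
#' @return a `sim_config`.
#' @export
sim_scenario <- function(which = c("confounded_plm", "logit_null",
                                   "logit_alt"), ...) {
  which <- match.arg(which)
  base <- switch(which,
    confounded_plm = list(n = 4000L, p = 200L, s = 10L, d1_type = "haz",
                          beta1 = -0.2, beta2 = 0.02),
    logit_null = list(n = 2000L, p = 100L, s = 5L, d1_type = "haz",
                      or2 = 1),
    logit_alt = list(n = 6000L, p = 200L, s = 10L, d1_type = "haz",
                     or2 = 1.03))
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# Quadratic growth-faltering mean curve, calibrated by an additive offset so
# that the expected 36-59-month mean equals the configured target under
# discrete-uniform ages. Strictly decreasing up to the vertex (35.5 months),
# increasing after.
.haz_curve <- function(age, config) {
  m0 <- function(a) {
    config$haz_bottom +
      config$haz_rise * ((a - config$haz_vertex) / config$haz_vertex)^2
  }
  offset <- config$haz_36_59_mean - mean(m0(36:59))
  m0(age) + offset
}

# Population-mean-preserving rural/urban HAZ offsets.
.haz_area_offset <- function(rural, config) {
  -config$haz_rural_gap * (rural - config$rural_share)
}

#' Generate the high-dimensional control table
#'
#' Builds exactly `p` control columns: demographic and household structure
#' variables (age in months and its square, sex, household size, dependency
#' ratios, mother's age at birth, birth order, head's education), wealth
#' quintile dummies, region, ethnicity and religion dummies, a rural flag,
#' media-exposure and union-type indicators, a bank of binary asset-style
#' indicators with heterogeneous prevalences, and rural-interaction copies of
#' non-age columns. A fixed named subset forms the low-dimensional ad-hoc
#' control set.
#'
#' @param config a [sim_config()]. Covariates use the RNG stream as-is; use
#'   [simulate_ecd()] for seeded end-to-end generation.
#' @return list with `Z` (numeric n x p matrix), `x_cols` (ad-hoc subset
#'   names), `asset_cols` (support-eligible asset columns), `prevalence`
#'   (named Bernoulli prevalences of the asset columns).
#' @export
gen_covariates <- function(config) {
  n <- config$n; p <- config$p
  base <- list()
  base$female <- stats::rbinom(n, 1, 0.49)
  base$age_months <- sample(0:59, n, replace = TRUE)
  base$age_sq <- base$age_months^2
  base$rural <- stats::rbinom(n, 1, config$rural_share)
  region <- sample.int(length(config$region_probs), n, replace = TRUE,
                       prob = config$region_probs)
  for (r in 2:length(config$region_probs)) {
    base[[paste0("region_", r)]] <- as.integer(region == r)
  }
  base$hh_size <- 2L + stats::rpois(n, 4.5)
  base$dep_ratio_young <- round(2 * stats::rbeta(n, 2, 2), 3)
  base$dep_ratio_old <- round(stats::rbeta(n, 1, 6), 3)
  wq <- sample.int(5L, n, replace = TRUE)
  for (qq in 2:5) base[[paste0("wealth_q", qq)]] <- as.integer(wq == qq)
  base$mother_age_birth <- round(pmin(pmax(stats::rnorm(n, 26, 6), 15), 45), 1)
  base$birth_order <- 1L + stats::rpois(n, 2)
  base$head_edu_years <- pmin(pmax(round(stats::rnorm(n, 5, 4)), 0L), 18L)
  base$mother_reads_news <- stats::rbinom(n, 1, 0.15)
  base$mother_radio <- stats::rbinom(n, 1, 0.40)
  base$mother_tv <- stats::rbinom(n, 1, 0.30)
  base$child_of_head <- stats::rbinom(n, 1, 0.80)
  base$polygynous_union <- stats::rbinom(n, 1, 0.25)
  base$wife_beating_attitude <- stats::rbinom(n, 1, 0.30)
  base$mosquito_nets <- stats::rpois(n, 1.5)
  eth <- sample.int(8L, n, replace = TRUE,
                    prob = c(0.3, 0.2, 0.15, 0.1, 0.1, 0.06, 0.05, 0.04))
  for (e in 2:8) base[[paste0("ethnicity_", e)]] <- as.integer(eth == e)
  rel <- sample.int(3L, n, replace = TRUE, prob = c(0.5, 0.45, 0.05))
  for (e in 2:3) base[[paste0("religion_", e)]] <- as.integer(rel == e)

  b0 <- length(base)                     # 35 structural columns
  m_min <- 3L * config$s + 5L            # head-room for disjoint supports
  m <- max(m_min, ceiling((p - b0 - (b0 - 3L)) / 2))
  if (b0 + m > p) m <- p - b0
  if (m < m_min) {
    stop(sprintf(paste0("p = %d is too small: need at least %d columns ",
                        "(%d structural + %d assets for s = %d)"),
                 p, b0 + m_min, b0, m_min, config$s), call. = FALSE)
  }
  prev <- stats::runif(m, 0.05, 0.95)
  asset_cols <- sprintf("asset_%03d", seq_len(m))
  assets <- matrix(stats::rbinom(n * m, 1, rep(prev, each = n)), n, m,
                   dimnames = list(NULL, asset_cols))
  names(prev) <- asset_cols

  Z <- cbind(do.call(cbind, base), assets)
  colnames(Z)[seq_len(b0)] <- names(base)

  n_inter <- p - ncol(Z)
  eligible <- setdiff(colnames(Z), c("age_months", "age_sq", "rural"))
  if (n_inter > length(eligible)) {
    stop("p too large for the structural layout", call. = FALSE)
  }
  if (n_inter > 0) {
    icols <- eligible[seq_len(n_inter)]
    inter <- Z[, icols, drop = FALSE] * Z[, "rural"]
    colnames(inter) <- paste0("rural_x_", icols)
    Z <- cbind(Z, inter)
  }
  stopifnot(ncol(Z) == p)
  x_cols <- c("female", "age_months", "age_sq", "hh_size",
              "dep_ratio_young", "dep_ratio_old",
              paste0("wealth_q", 2:5), "rural",
              paste0("region_", 2:length(config$region_probs)))
  list(Z = Z, x_cols = x_cols, asset_cols = asset_cols, prevalence = prev)
}

# Draw the sparse supports and coefficients of the nuisance functions
# f (outcome), g (HAZ) and h (education). The confounded components of g and
# h live on f's support with positive signs (wealth-like factors raise the
# development score, stature and schooling together); each treatment also
# has an own disjoint support with random signs.
.gen_truth_coefs <- function(cov, config) {
  s <- config$s
  pool <- cov$asset_cols
  if (length(pool) < 3L * s) stop("not enough asset columns for supports",
                                  call. = FALSE)
  picks <- sample(pool, 3L * s)
  S_f <- picks[seq_len(s)]
  S_g <- picks[s + seq_len(s)]
  S_h <- picks[2L * s + seq_len(s)]
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  list(
    S_f = S_f, S_g_own = S_g, S_h_own = S_h,
    theta_f = stats::setNames(stats::runif(s, 0.4, 0.8), S_f),
    theta_g_shared = stats::setNames(
      config$confounding * stats::runif(s, 0.25, 0.5), S_f),
    theta_g_own = stats::setNames(sgn(s) * stats::runif(s, 0.25, 0.5), S_g),
    theta_h_shared = stats::setNames(
      config$confounding * stats::runif(s, 0.8, 1.5), S_f),
    theta_h_own = stats::setNames(sgn(s) * stats::runif(s, 0.8, 1.5), S_h),
    var_z = cov$prevalence * (1 - cov$prevalence)
  )
}

# centered sparse linear combination of asset columns
.sparse_lincomb <- function(Z, theta, prevalence) {
  cols <- names(theta)
  drop(sweep(Z[, cols, drop = FALSE], 2L, prevalence[cols]) %*% theta)
}

#' Generate treatments and structural outcomes given covariates
#'
#' HAZ follows the calibrated growth-faltering age curve plus a rural
#' offset, a sparse confounded control signal g(Z) and Gaussian noise (plus
#' an education channel in the mediation regime); stunting is HAZ <= -2.
#' Maternal education is a rural/urban mixture plus a sparse control signal
#' h(Z) and noise, rounded and censored to whole years 0--18 (a latent
#' continuous copy is kept). The continuous development score is the
#' partially linear outcome `beta1 D1 + beta2 edu + f(Z) + e`; the binary
#' on-track outcome is Bernoulli with logit index
#' `a0 + log(or1) D1 + log(or2) edu + f(Z)`, intercept calibrated to the
#' target prevalence.
#'
#' @param cov output of [gen_covariates()].
#' @param config the same [sim_config()].
#' @return list with `data` (data.frame of treatments and outcomes) and
#'   `truth` (supports, coefficients, calibration constants).
#' @export
gen_structural <- function(cov, config) {
  Z <- cov$Z; n <- nrow(Z)
  tr <- .gen_truth_coefs(cov, config)
  age <- Z[, "age_months"]; rural <- Z[, "rural"]

  g_z <- .sparse_lincomb(Z, c(tr$theta_g_shared, tr$theta_g_own),
                         cov$prevalence)
  h_z <- .sparse_lincomb(Z, c(tr$theta_h_shared, tr$theta_h_own),
                         cov$prevalence)
  f_z <- .sparse_lincomb(Z, tr$theta_f, cov$prevalence)

  edu_mean_pop <- config$rural_share * config$edu_rural_mean +
    (1 - config$rural_share) * config$edu_urban_mean
  edu_base <- ifelse(rural == 1, config$edu_rural_mean, config$edu_urban_mean)
  edu_latent <- edu_base + h_z + stats::rnorm(n, 0, config$edu_sd)
  edu_years <- if (config$edu_integer) {
    pmin(pmax(round(edu_latent), 0), 18)
  } else edu_latent

  haz <- .haz_curve(age, config) + .haz_area_offset(rural, config) + g_z +
    stats::rnorm(n, 0, config$haz_noise_sd)
  if (config$regime == "mediation") {
    haz <- haz + config$channel * (edu_years - edu_mean_pop)
  }
  stunted <- as.integer(haz <= -2)
  d1 <- if (config$d1_type == "stunted") stunted else haz

  y_ecdi <- config$beta1 * d1 + config$beta2 * edu_years + f_z +
    stats::rnorm(n, 0, config$sigma_y)

  eta0 <- log(config$or1) * d1 + log(config$or2) * edu_years + f_z
  a0 <- stats::uniroot(function(a) mean(stats::plogis(a + eta0)) -
                         config$p_ontrack,
                       interval = c(-30, 30), tol = 1e-10)$root
  y_ontrack <- stats::rbinom(n, 1, stats::plogis(a0 + eta0))

  tr$a0_bin <- a0
  tr$beta1 <- config$beta1; tr$beta2 <- config$beta2
  tr$or1 <- config$or1; tr$or2 <- config$or2
  tr$d1_type <- config$d1_type
  tr$edu_mean_pop <- edu_mean_pop
  list(data = data.frame(haz = haz, stunted = stunted,
                         edu_years = edu_years, edu_latent = edu_latent,
                         y_ecdi = y_ecdi, y_ontrack = y_ontrack, f_z = f_z),
       truth = tr)
}

#' Generate item-level ECD responses from a latent score
#'
#' Each of the ten items is Bernoulli with probability
#' `plogis(a_domain + b * latent)`; the per-domain intercepts are calibrated
#' by root-finding so that the expected domain on-track share over the
#' supplied latent sample equals the configured target (defaults are the
#' published full-sample shares 0.30 / 0.92 / 0.79 / 0.72).
#'
#' @param latent standardized latent development score (mean ~0, SD ~1).
#' @param config a [sim_config()] (fields `item_targets`, `item_slope`).
#' @return list with `items` (n x 10 matrix, columns `lit_1..3`, `phy_1..2`,
#'   `lrn_1..2`, `soc_1..3`) and `calibration` (per-domain intercepts).
#' @export
gen_items <- function(latent, config) {
  b <- config$item_slope
  targets <- config$item_targets
  stopifnot(all(names(ecd_domains) %in% names(targets)))
  # P(on track | item prob p) for "at least t of k" rules
  ontrack_prob <- function(p, k, t) {
    stats::pbinom(t - 1L, k, p, lower.tail = FALSE)
  }
  k_dom <- unlist(ecd_domains)
  t_dom <- .domain_threshold[names(ecd_domains)]
  a_dom <- vapply(names(ecd_domains), function(dm) {
    target <- targets[[dm]]
    fn <- function(a) {
      p <- stats::plogis(a + b * latent)
      mean(ontrack_prob(p, k_dom[[dm]], t_dom[[dm]])) - target
    }
    stats::uniroot(fn, interval = c(-20, 20), tol = 1e-10)$root
  }, numeric(1))
  prefix <- c(literacy = "lit", physical = "phy", learning = "lrn",
              socioemotional = "soc")
  items <- do.call(cbind, lapply(names(ecd_domains), function(dm) {
    k <- k_dom[[dm]]
    p <- stats::plogis(a_dom[[dm]] + b * latent)
    m <- matrix(stats::rbinom(length(latent) * k, 1, rep(p, k)),
                ncol = k)
    colnames(m) <- paste0(prefix[[dm]], "_", seq_len(k))
    m
  }))
  list(items = items, calibration = list(a_dom = a_dom, b = b))
}

#' Age profile of HAZ (growth faltering)
#'
#' Samples ages uniformly on 0--59 months and HAZ values on the calibrated
#' mean curve (strictly decreasing to 35 months, recovering after) plus
#' Gaussian noise, optionally with the population-mean-preserving
#' rural/urban offset.
#'
#' @param n number of children.
#' @param config a [sim_config()].
#' @param rural_offset include the rural/urban level difference (adds a
#'   `rural` column).
#' @param noise_sd noise SD (defaults to the config's HAZ noise).
#' @return data.frame with `age_months`, `haz` and (optionally) `rural`.
#' @export
gen_age_profile <- function(n, config = sim_config(), rural_offset = FALSE,
                            noise_sd = config$haz_noise_sd) {
  age <- sample(0:59, n, replace = TRUE)
  haz <- .haz_curve(age, config)
  out <- data.frame(age_months = age)
  if (rural_offset) {
    out$rural <- stats::rbinom(n, 1, config$rural_share)
    haz <- haz + .haz_area_offset(out$rural, config)
  }
  out$haz <- haz + stats::rnorm(n, 0, noise_sd)
  out
}

#' Simulate a complete MICS-like dataset
#'
#' Runs [gen_covariates()], [gen_structural()] and [gen_items()] under a
#' single seed and assembles the child-level analysis table: the expanded
#' control columns, the ad-hoc subset, treatments (`haz`, `stunted`,
#' `edu_years`), structural outcomes (`y_ecdi` continuous, `y_ontrack`
#' binary), and item-level ECD responses plus scored outcomes
#' (`ontrack_*`, `unicef_ontrack`, `total_score`, `ecdi_z`) for children
#' 36--59 months old (missing below 36 months, as in the survey).
#'
#' @param config a [sim_config()].
#' @return object of class `ecd_sim`: list with `data`, `truth`, `x_cols`,
#'   `z_cols`, `config`.
#' @export
simulate_ecd <- function(config = sim_config()) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed, kind = "Mersenne-Twister")
  cov <- gen_covariates(config)
  str <- gen_structural(cov, config)
  data <- cbind(data.frame(child_id = seq_len(config$n)),
                as.data.frame(cov$Z), str$data)

  older <- data$age_months >= 36
  latent <- rep(NA_real_, config$n)
  y_old <- data$y_ecdi[older]
  latent[older] <- (y_old - mean(y_old)) / stats::sd(y_old)
  it <- gen_items(latent[older], config)
  item_cols <- colnames(it$items)
  for (cc in item_cols) data[[cc]] <- NA_integer_
  data[older, item_cols] <- it$items
  scored <- score_ecd(it$items)
  for (cc in names(scored)) data[[cc]] <- NA_real_
  data[older, names(scored)] <- scored

  truth <- str$truth
  truth$item_calibration <- it$calibration
  truth$curve <- list(bottom = config$haz_bottom, rise = config$haz_rise,
                      vertex = config$haz_vertex,
                      offset = config$haz_36_59_mean -
                        mean(config$haz_bottom + config$haz_rise *
                               ((36:59 - config$haz_vertex) /
                                  config$haz_vertex)^2))
  truth$sigma_y <- config$sigma_y
  truth$sigma_edu <- config$edu_sd
  truth$haz_noise_sd <- config$haz_noise_sd
  truth$confounding <- config$confounding
  truth$regime <- config$regime
  truth$channel <- if (config$regime == "mediation") config$channel else 0
  structure(list(data = data, truth = truth, x_cols = cov$x_cols,
                 z_cols = colnames(cov$Z), item_cols = item_cols,
                 config = config),
            class = "ecd_sim")
}

#' @export
print.ecd_sim <- function(x, ...) {
  cat(sprintf(paste0("synthetic ECD dataset: n = %d children, %d controls ",
                     "(%d ad-hoc), regime %s, seed %d\n"),
              x$config$n, length(x$z_cols), length(x$x_cols),
              x$config$regime, x$config$seed))
  invisible(x)
}

#' Closed-form omitted-variable bias of the naive (ad-hoc) estimator
#'
#' For the continuous-treatment, continuous-education variant of the
#' partially linear scenario (`d1_type = "haz"`, `edu_integer = FALSE`,
#' regime `"plm"`), the confounding supports are independent of the ad-hoc
#' control set by construction, so the population bias of the naive OLS
#' treatment coefficients has the textbook closed form
#' `bias = M^-1 c(Cov(D1~, f), Cov(D2~, f))` with `M` the covariance of the
#' X-residualized treatments. All moments follow from the generator's truth
#' (independent Bernoulli supports).
#'
#' @param truth the `truth` element of a [simulate_ecd()] result.
#' @param config the matching `sim_config`.
#' @return named vector: asymptotic bias of the naive estimates of
#'   (beta1, beta2).
#' @export
analytic_naive_bias <- function(truth, config) {
  if (config$d1_type != "haz" || config$edu_integer ||
      config$regime != "plm") {
    stop("closed-form bias requires d1_type = 'haz', edu_integer = FALSE, ",
         "regime = 'plm'", call. = FALSE)
  }
  v <- truth$var_z
  vf <- v[names(truth$theta_f)]
  Vg <- sum(truth$theta_g_shared^2 * vf) +
    sum(truth$theta_g_own^2 * v[names(truth$theta_g_own)]) +
    config$haz_noise_sd^2
  Ve <- sum(truth$theta_h_shared^2 * vf) +
    sum(truth$theta_h_own^2 * v[names(truth$theta_h_own)]) +
    config$edu_sd^2
  Cgh <- sum(truth$theta_g_shared * truth$theta_h_shared * vf)
  Cgf <- sum(truth$theta_g_shared * truth$theta_f * vf)
  Chf <- sum(truth$theta_h_shared * truth$theta_f * vf)
  M <- matrix(c(Vg, Cgh, Cgh, Ve), 2, 2)
  bias <- solve(M, c(Cgf, Chf))
  stats::setNames(bias, c("d1", "d2"))
}
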