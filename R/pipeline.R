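# Config-driven orchestration: build outcome variables, run the ad-hoc and
# DML arms over outcome x subgroup x age-band grids on identical samples,
# and produce comparison tables and smoothed growth-faltering profiles.

# outcome registry: analysis name -> data column + family
.outcome_map <- function(name) {
  known <- list(
    ecdi = c("y_ecdi", "linear"),
    unicef = c("y_ontrack", "logit"),
    ecdi_items = c("ecdi_z", "linear"),
    unicef_items = c("unicef_ontrack", "logit"),
    literacy = c("ontrack_literacy", "logit"),
    physical = c("ontrack_physical", "logit"),
    learning = c("ontrack_learning", "logit"),
    socioemotional = c("ontrack_socioemotional", "logit"),
    haz = c("haz", "linear"),
    stunted = c("stunted", "logit")
  )
  if (name %in% names(known)) {
    list(column = known[[name]][1], family = known[[name]][2])
  } else {
    list(column = name, family = NA_character_)  # resolved against the data
  }
}

.ecd_outcomes <- c("ecdi", "unicef", "ecdi_items", "unicef_items",
                   "literacy", "physical", "learning", "socioemotional")

.parse_band <- function(band) {
  parts <- as.integer(strsplit(band, "-", fixed = TRUE)[[1]])
  if (length(parts) != 2L || any(is.na(parts))) {
    stop("age band must look like '36-59'", call. = FALSE)
  }
  parts
}

#' Compare ad-hoc and DML estimates over an analysis grid
#'
#' For every outcome x subgroup x age-band cell, fits the ad-hoc benchmark
#' (small fixed control set) and the DML arm (cross-fit partialling-out over
#' the expanded control set) on exactly the same records, with the linear
#' family for continuous outcomes and the logit family (odds ratios) for
#' binary ones. ECD outcomes are only defined for children 36--59 months old;
#' requesting them on a band that includes younger children is an error.
#' Cells whose sample is below `n_floor` are marked `insufficient_n` and the
#' run continues.
#'
#' @param x an `ecd_sim` from [simulate_ecd()], or a data.frame (then supply
#'   `x_cols` and `z_cols`).
#' @param outcomes analysis outcome names (see Details) or data columns.
#' @param treatments treatment columns (1 or 2).
#' @param subgroups any of `"all"`, `"urban"`, `"rural"`.
#' @param age_bands age bands as `"lo-hi"` strings (months).
#' @param K,R,seed fold plan parameters for the DML arm.
#' @param lambda penalty rule for the DML nuisances.
#' @param n_floor minimum cell size.
#' @param x_cols,z_cols control column names when `x` is a data.frame.
#' @return a `comparison_table`: data.frame with one row per cell x
#'   treatment, columns `outcome`, `subgroup`, `age_band`, `family`, `term`,
#'   `n`, `adhoc_estimate`, `adhoc_p`, `dml_estimate`, `dml_p` (estimates
#'   are odds ratios for the logit family), `status`; metadata in
#'   attributes `"meta"` and (for synthetic input with matching treatments)
#'   `"truth_comparison"`.
#' @details Outcome names `ecdi` (continuous score), `unicef` (binary
#'   on-track), `ecdi_items`/`unicef_items` (scored from items), the four
#'   domain flags, `haz` and `stunted` map to the generator's columns; any
#'   other name is used as a data column directly (binary columns get the
#'   logit family).
#' @export
run_comparison <- function(x, outcomes = c("ecdi", "unicef"),
                           treatments = c("stunted", "edu_years"),
                           subgroups = "all", age_bands = "36-59",
                           K = 10L, R = 5L, seed = 1L, lambda = "plugin",
                           n_floor = 200L, x_cols = NULL, z_cols = NULL) {
  if (inherits(x, "ecd_sim")) {
    data <- x$data; x_cols <- x$x_cols; z_cols <- x$z_cols
    truth <- x$truth; d1_col <- if (x$config$d1_type == "stunted")
      "stunted" else "haz"
  } else {
    data <- as.data.frame(x); truth <- NULL; d1_col <- NULL
    if (is.null(x_cols) || is.null(z_cols)) {
      stop("supply x_cols and z_cols with a raw data.frame", call. = FALSE)
    }
  }
  stopifnot(length(treatments) %in% 1:2)
  subgroups <- match.arg(subgroups, c("all", "urban", "rural"),
                         several.ok = TRUE)

  # resolve outcomes and validate the whole request before fitting anything
  specs <- lapply(outcomes, function(o) {
    m <- .outcome_map(o)
    if (!m$column %in% names(data)) {
      stop(sprintf("outcome '%s' (column '%s') not found; available: %s",
                   o, m$column,
                   paste(utils::head(setdiff(names(data), z_cols), 40),
                         collapse = ", ")), call. = FALSE)
    }
    if (is.na(m$family)) {
      vals <- unique(stats::na.omit(data[[m$column]]))
      m$family <- if (all(vals %in% c(0, 1))) "logit" else "linear"
    }
    c(name = o, column = m$column, family = m$family)
  })
  for (band in age_bands) {
    rng <- .parse_band(band)
    if (rng[1] < 36 && any(outcomes %in% .ecd_outcomes)) {
      stop(sprintf(paste0("ECD outcomes are only measured for children ",
                          "36-59 months old; age band '%s' includes ",
                          "younger children"), band), call. = FALSE)
    }
  }
  missing_t <- setdiff(treatments, names(data))
  if (length(missing_t)) {
    stop("treatment column(s) not found: ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  }

  rows <- list(); truth_rows <- list(); cells <- list()
  for (sp in specs) for (sg in subgroups) for (band in age_bands) {
    cell <- .fit_cell(data, outcome = sp, treatments = treatments,
                      subgroup = sg, band = band, x_cols = x_cols,
                      z_cols = z_cols, K = K, R = R, seed = seed,
                      lambda = lambda, n_floor = n_floor)
    rows[[length(rows) + 1L]] <- cell$rows
    cells[[length(cells) + 1L]] <- cell$meta
    if (!is.null(truth) && cell$meta$status == "ok" &&
        identical(sort(treatments), sort(c(d1_col, "edu_years"))) &&
        sp[["name"]] %in% c("ecdi", "unicef")) {
      tv <- if (sp[["name"]] == "ecdi") {
        c(truth$beta1, truth$beta2)[match(treatments, c(d1_col, "edu_years"))]
      } else {
        c(log(truth$or1), log(truth$or2))[match(treatments,
                                                c(d1_col, "edu_years"))]
      }
      est <- cell$log_scale_estimates
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        outcome = sp[["name"]], subgroup = sg, age_band = band,
        term = treatments, truth = tv,
        adhoc_error = abs(est$adhoc - tv), dml_error = abs(est$dml - tv))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  attr(out, "meta") <- list(K = K, R = R, seed = seed,
                            lambda_rule = if (is.character(lambda)) lambda
                                          else "fixed",
                            cells = cells)
  if (length(truth_rows)) {
    tc <- do.call(rbind, truth_rows)
    tc$dml_closer <- tc$dml_error < tc$adhoc_error
    attr(out, "truth_comparison") <- tc
  }
  out
}

# Fit a single grid cell: identical record set for both arms.
.fit_cell <- function(data, outcome, treatments, subgroup, band, x_cols,
                      z_cols, K, R, seed, lambda, n_floor) {
  rng <- .parse_band(band)
  keep <- data$age_months >= rng[1] & data$age_months <= rng[2]
  if (subgroup == "urban") keep <- keep & data$rural == 0
  if (subgroup == "rural") keep <- keep & data$rural == 1
  # drop the rural flag and its interactions when the subgroup fixes area
  xc <- x_cols; zc <- z_cols
  if (subgroup != "all") {
    xc <- setdiff(xc, "rural")
    zc <- setdiff(zc, c("rural", grep("^rural_x_", zc, value = TRUE)))
  }
  xc <- setdiff(xc, treatments); zc <- setdiff(zc, treatments)
  used <- c(outcome[["column"]], treatments, xc, zc)
  keep <- keep & stats::complete.cases(data[, used, drop = FALSE])
  df <- data[keep, , drop = FALSE]
  n <- nrow(df)
  base_row <- data.frame(outcome = outcome[["name"]], subgroup = subgroup,
                         age_band = band, family = outcome[["family"]],
                         term = treatments, n = n,
                         adhoc_estimate = NA_real_, adhoc_p = NA_real_,
                         dml_estimate = NA_real_, dml_p = NA_real_,
                         status = "insufficient_n")
  meta <- list(outcome = outcome[["name"]], subgroup = subgroup,
               age_band = band, n = n,
               rows_checksum = sum(which(keep)), status = "insufficient_n")
  if (n < n_floor) {
    return(list(rows = base_row, meta = meta, log_scale_estimates = NULL))
  }

  y <- df[[outcome[["column"]]]]
  fam <- outcome[["family"]]
  spec <- adhoc_spec(outcome[["column"]], treatments, xc, family = fam)
  plan <- make_folds(n, K = K, R = R, seed = seed,
                     stratify = if (fam == "logit") y else NULL)
  Z <- as.matrix(df[, zc, drop = FALSE])
  D <- as.matrix(df[, treatments, drop = FALSE])
  res <- tryCatch({
    if (fam == "linear") {
      adhoc <- fit_linear_adhoc(df, spec)
      dml <- crossfit_plm(y, D, Z, plan, lambda = lambda)
    } else {
      adhoc <- fit_logit_adhoc(df, spec)
      dml <- crossfit_logit(y, D, Z, plan, lambda = lambda)
    }
    list(adhoc = adhoc, dml = dml)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    base_row$status <- paste0("error: ", conditionMessage(res))
    meta$status <- "error"
    return(list(rows = base_row, meta = meta, log_scale_estimates = NULL))
  }
  a <- res$adhoc$coefficients; d <- res$dml$coefficients
  base_row$adhoc_estimate <- if (fam == "logit") a$odds_ratio else a$estimate
  base_row$adhoc_p <- a$p_value
  base_row$dml_estimate <- if (fam == "logit") d$odds_ratio else d$estimate
  base_row$dml_p <- d$p_value
  base_row$status <- "ok"
  meta$status <- "ok"
  meta$selection_counts <- res$dml$selection$count
  list(rows = base_row, meta = meta,
       log_scale_estimates = list(adhoc = a$estimate, dml = d$estimate))
}

#' Effect of maternal education on nutritional outcomes
#'
#' Single-treatment runs of the comparison grid: education as the only
#' treatment, HAZ (linear) and stunting (logit, odds ratios) as outcomes,
#' across subgroups and the full/older/younger age bands.
#'
#' @inheritParams run_comparison
#' @param treatment the education column.
#' @return a `comparison_table` (see [run_comparison()]).
#' @export
run_nutrition <- function(x, outcomes = c("haz", "stunted"),
                          treatment = "edu_years",
                          subgroups = c("all", "rural", "urban"),
                          age_bands = c("0-59", "36-59", "0-35"),
                          K = 10L, R = 5L, seed = 1L, lambda = "plugin",
                          n_floor = 200L, x_cols = NULL, z_cols = NULL) {
  run_comparison(x, outcomes = outcomes, treatments = treatment,
                 subgroups = subgroups, age_bands = age_bands, K = K, R = R,
                 seed = seed, lambda = lambda, n_floor = n_floor,
                 x_cols = x_cols, z_cols = z_cols)
}

#' @export
print.comparison_table <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("ad-hoc vs DML comparison (K = %d, R = %d, lambda = %s)\n",
              meta$K, meta$R, meta$lambda_rule))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Smoothed age profile of HAZ (growth faltering curve)
#'
#' Kernel-weighted local mean (local polynomial of degree 0) of HAZ against
#' age in months, with an Epanechnikov kernel on an evenly spaced grid --
#' the standard way to display growth faltering. Grid points with no kernel
#' mass are returned as missing.
#'
#' @param age numeric vector of ages (months).
#' @param haz numeric vector of HAZ values.
#' @param bandwidth kernel half-width in months; default is the
#'   Epanechnikov rule-of-thumb `2.34 * sd(age) * n^(-1/5)`.
#' @param grid evaluation points; default 60 points over the age range.
#' @param by optional grouping vector (e.g. rural flag) for per-group
#'   profiles.
#' @return data.frame of class `smoothed_profile` with columns `grid`,
#'   `estimate`, `n_local` (observations with positive weight) and, when
#'   `by` is given, `group`; the bandwidth is stored as an attribute.
#' @export
growth_faltering_profile <- function(age, haz, bandwidth = NULL, grid = NULL,
                                     by = NULL) {
  ok <- is.finite(age) & is.finite(haz)
  if (!is.null(by)) ok <- ok & !is.na(by)
  age <- age[ok]; haz <- haz[ok]; if (!is.null(by)) by <- by[ok]
  if (length(age) < 30L) stop("need at least 30 observations", call. = FALSE)
  if (is.null(bandwidth)) {
    bandwidth <- 2.34 * stats::sd(age) * length(age)^(-1 / 5)
  }
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be positive", call. = FALSE)
  }
  if (is.null(grid)) grid <- seq(min(age), max(age), length.out = 60L)

  smooth_one <- function(a, h) {
    vapply(grid, function(x0) {
      u <- (a - x0) / bandwidth
      w <- ifelse(abs(u) < 1, 0.75 * (1 - u^2), 0)
      sw <- sum(w)
      if (sw <= 0) NA_real_ else sum(w * h) / sw
    }, numeric(1))
  }
  nloc_one <- function(a) {
    vapply(grid, function(x0) sum(abs((a - x0) / bandwidth) < 1), integer(1))
  }
  if (is.null(by)) {
    out <- data.frame(grid = grid, estimate = smooth_one(age, haz),
                      n_local = nloc_one(age))
  } else {
    out <- do.call(rbind, lapply(split(seq_along(age), by), function(idx) {
      data.frame(group = by[idx[1]], grid = grid,
                 estimate = smooth_one(age[idx], haz[idx]),
                 n_local = nloc_one(age[idx]))
    }))
    rownames(out) <- NULL
  }
  attr(out, "bandwidth") <- bandwidth
  class(out) <- c("smoothed_profile", "data.frame")
  out
}

#' Write a comparison table to CSV with a JSON metadata sidecar
#'
#' @param tab a `comparison_table`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return invisibly, the paths written.
#' @export
write_comparison <- function(tab, dir, name = "comparison") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(name, ".csv"))
  js <- file.path(dir, paste0(name, "_meta.json"))
  utils::write.csv(as.data.frame(tab), csv, row.names = FALSE)
  meta <- attr(tab, "meta")
  meta$cells <- lapply(meta$cells, function(cl) {
    cl$selection_counts <- if (!is.null(cl$selection_counts))
      as.data.frame(cl$selection_counts)
    cl
  })
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(csv = csv, json = js))
}
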