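#' Specify an ad-hoc benchmark regression
#'
#' The conventional specification: outcome regressed on one or two treatment
#' variables (child stature and/or mother's education) plus a small, fixed,
#' hand-picked control set entering linearly. Serves as the benchmark against
#' which the DML arm is contrasted.
#'
#' @param outcome name of the outcome column.
#' @param treatments character vector (length 1 or 2) of treatment columns.
#' @param controls character vector of control columns (must not contain any
#'   treatment).
#' @param family `"linear"` for least squares, `"logit"` for logistic
#'   regression reported as odds ratios.
#' @return an object of class `adhoc_spec`.
#' @export
adhoc_spec <- function(outcome, treatments, controls,
                       family = c("linear", "logit")) {
  family <- match.arg(family)
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.character(treatments), length(treatments) %in% 1:2,
            is.character(controls))
  dup <- intersect(treatments, controls)
  if (length(dup)) {
    stop("treatment variable(s) also listed as controls: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (outcome %in% c(treatments, controls)) {
    stop("outcome cannot appear among treatments or controls", call. = FALSE)
  }
  structure(list(outcome = outcome, treatments = treatments,
                 controls = controls, family = family),
            class = "adhoc_spec")
}

# Build the design matrix for an adhoc fit; drops aliased control columns
# (never treatments) found by pivoted QR and records the drops.
.adhoc_design <- function(data, spec) {
  need <- c(spec$outcome, spec$treatments, spec$controls)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data[, need, drop = FALSE]
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  y <- df[[spec$outcome]]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(df[, c(spec$treatments, spec$controls), drop = FALSE]))
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    if (any(spec$treatments %in% dropped)) {
      stop("design is rank deficient on a treatment column: ",
           paste(intersect(spec$treatments, dropped), collapse = ", "),
           call. = FALSE)
    }
    X <- X[, sort(keep), drop = FALSE]
  }
  list(y = y, X = X, n = sum(cc), dropped = dropped)
}

# Assemble the per-treatment results table shared by both arms.
.estimation_result <- function(est, se, treatments, family, n, method,
                               dropped = character(0), extra = list()) {
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  lo <- est + stats::qnorm(0.025) * se
  hi <- est + stats::qnorm(0.975) * se
  tab <- data.frame(term = treatments, estimate = est, std_error = se,
                    statistic = z, p_value = p,
                    conf_low = lo, conf_high = hi, row.names = NULL)
  if (family == "logit") {
    tab$odds_ratio <- exp(est)
    tab$or_conf_low <- exp(lo)
    tab$or_conf_high <- exp(hi)
  }
  structure(c(list(coefficients = tab, n = n, family = family,
                   method = method, dropped = dropped), extra),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("%s %s estimation (n = %d)\n",
              switch(x$method, adhoc = "Ad-hoc", dml = "DML", x$method),
              x$family, x$n))
  tab <- x$coefficients
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 4)
  print(tab, row.names = FALSE)
  if (length(x$dropped)) {
    cat("dropped collinear columns:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ad-hoc linear regression of an ECD outcome on treatments and controls
#'
#' Least squares with heteroskedasticity-robust (HC1) standard errors. The
#' treatment coefficients estimate partial correlations with the outcome net
#' of the fixed control set; with a small hand-picked control set they carry
#' no causal guarantee (omitted-variable bias is the failure mode the DML arm
#' addresses).
#'
#' @param data data.frame of child records.
#' @param spec an [adhoc_spec()] with `family = "linear"`.
#' @return an `estimation_result` with one row per treatment.
#' @export
fit_linear_adhoc <- function(data, spec) {
  stopifnot(inherits(spec, "adhoc_spec"))
  if (spec$family != "linear") stop("spec family must be 'linear'", call. = FALSE)
  d <- .adhoc_design(data, spec)
  fit <- stats::lm.fit(d$X, d$y)
  V <- .hc1_lm(d$X, fit$residuals)
  idx <- match(spec$treatments, colnames(d$X))
  .estimation_result(est = unname(fit$coefficients[idx]),
                     se = sqrt(diag(V))[idx],
                     treatments = spec$treatments, family = "linear",
                     n = d$n, method = "adhoc", dropped = d$dropped,
                     extra = list(interpretation = "partial correlation",
                                  vcov_type = "HC1"))
}

# HC1 sandwich for a least-squares fit given design and residuals.
.hc1_lm <- function(X, resid) {
  n <- nrow(X); k <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  meat <- crossprod(X * resid)
  (n / (n - k)) * XtXinv %*% meat %*% XtXinv
}

#' Ad-hoc logistic regression reported as odds ratios
#'
#' Maximum-likelihood logit of a binary outcome on treatments plus the fixed
#' control set; treatment effects are reported as odds ratios exp(coef) with
#' Wald (delta-method) confidence intervals on the log-odds scale and
#' heteroskedasticity-robust (HC1) standard errors.
#'
#' @inheritParams fit_linear_adhoc
#' @param spec an [adhoc_spec()] with `family = "logit"`.
#' @return an `estimation_result`; `coefficients$estimate` is on the log-odds
#'   scale, `coefficients$odds_ratio` is exp(estimate).
#' @export
fit_logit_adhoc <- function(data, spec) {
  stopifnot(inherits(spec, "adhoc_spec"))
  if (spec$family != "logit") stop("spec family must be 'logit'", call. = FALSE)
  d <- .adhoc_design(data, spec)
  yvals <- unique(d$y[!is.na(d$y)])
  if (!all(yvals %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (length(yvals) < 2L) stop("outcome is constant; logit undefined", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(d$X, d$y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  if (!fit$converged) stop("logit did not converge in 100 iterations", call. = FALSE)
  co <- fit$coefficients
  big <- abs(co[-1]) > 12           # intercept exempt; logit scale
  if (any(big, na.rm = TRUE)) {
    stop("possible complete separation on column(s): ",
         paste(names(co[-1])[which(big)], collapse = ", "), call. = FALSE)
  }
  p <- fit$fitted.values
  w <- p * (1 - p)
  bread <- chol2inv(chol(crossprod(d$X * sqrt(w))))
  meat <- crossprod(d$X * (d$y - p))
  n <- d$n; k <- ncol(d$X)
  V <- (n / (n - k)) * bread %*% meat %*% bread
  idx <- match(spec$treatments, colnames(d$X))
  .estimation_result(est = unname(co[idx]), se = sqrt(diag(V))[idx],
                     treatments = spec$treatments, family = "logit",
                     n = n, method = "adhoc", dropped = d$dropped,
                     extra = list(vcov_type = "HC1"))
}

#' Convert an odds ratio to a percent change in odds
#'
#' `100 * (OR - 1)`: an odds ratio of 0.711 is a -28.9% change in the odds,
#' 1.0 is no change.
#'
#' @param odds_ratio positive numeric vector.
#' @return percent change in the odds.
#' @examples
#' or_to_percent(0.711)  # -28.9
#' or_to_percent(1)      # 0
#' @export
or_to_percent <- function(odds_ratio) {
  if (any(!is.finite(odds_ratio)) || any(odds_ratio <= 0)) {
    stop("odds ratios must be positive and finite", call. = FALSE)
  }
  100 * (odds_ratio - 1)
}
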