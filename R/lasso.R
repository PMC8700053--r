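# LASSO nuisance fits. The solvers are glmnet's coordinate descent; this file
# owns the lambda rules, internal standardization conventions, post-LASSO
# refits and out-of-fold prediction bookkeeping used by the cross-fit engine.

# Deterministic CV fold labels: systematic assignment over the training rows
# in their natural order. Rows reaching a training set have already been
# randomized by the fold plan, and a non-random assignment keeps estimates
# exactly invariant to relabeling of cross-fit folds and reproducible from
# the plan seed alone.
.cv_foldid <- function(n, nfolds = 10L) rep_len(seq_len(nfolds), n)

# lambda for the plugin rule: c * sigma * qnorm(1 - gamma/(2p)) / sqrt(n),
# on glmnet's per-observation objective scale, with c = 1.1, gamma = 0.1.
.plugin_lambda <- function(sigma, n, p, c = 1.1, gamma = 0.1) {
  c * sigma * stats::qnorm(1 - gamma / (2 * max(p, 1))) / sqrt(n)
}

.drop_constant <- function(x) {
  if (is.null(x) || ncol(x) == 0L) return(x)
  keep <- vapply(seq_len(ncol(x)), function(j) {
    col <- x[, j]
    any(col != col[1L])            # early exit on the first differing value
  }, logical(1))
  x[, keep, drop = FALSE]
}

#' LASSO regression nuisance fit with post-selection refit
#'
#' Fits an l1-penalized least-squares regression of a nuisance target
#' (outcome or treatment) on the high-dimensional control matrix, selects the
#' penalty by cross-validation or a plugin rule, and predicts on new records
#' using an unpenalized refit on the selected columns (post-LASSO), falling
#' back to the penalized coefficients if the refit is rank deficient.
#' Controls are standardized internally before penalization; coefficients are
#' reported on the original scale. All-constant (or empty) control matrices
#' give a valid intercept-only fit whose predictions are the (weighted)
#' training mean.
#'
#' @param z numeric matrix of controls (training rows).
#' @param y numeric target vector.
#' @param z_new optional matrix of controls to predict on.
#' @param lambda `"cv"` (10-fold cross-validated, deterministic fold labels),
#'   `"plugin"` (1.1 * sigma_hat * qnorm(1 - 0.1/(2p)) / sqrt(n)), or a fixed
#'   non-negative number on glmnet's scale (`0` = ordinary least squares on
#'   all columns, `Inf` = intercept only).
#' @param weights optional non-negative observation weights.
#' @param target label stored on the fit (e.g. `"Y"`, `"D1"`).
#' @param post logical: use the post-LASSO refit for predictions.
#' @return object of class `nuisance_fit`: `selected` (column names),
#'   `lambda`, `coef_lasso` (penalized, original scale), `coef_post` (refit,
#'   or NULL), `fitted_new` (predictions for `z_new`), `target`, `n_train`.
#' @export
lasso_linear <- function(z, y, z_new = NULL, lambda = "cv", weights = NULL,
                         target = "y", post = TRUE) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  if (!is.null(z)) z <- as.matrix(z)
  z_eff <- .drop_constant(z)
  p <- if (is.null(z_eff)) 0L else ncol(z_eff)

  wmean <- function(v) sum(weights * v) / sum(weights)

  # resolve the penalty level
  lam <- NA_real_
  if (is.character(lambda)) {
    rule <- match.arg(lambda, c("cv", "plugin"))
  } else {
    rule <- "fixed"; lam <- as.numeric(lambda)
    if (!is.finite(lam) && lam > 0) rule <- "inf"
    if (is.finite(lam) && lam < 0) stop("lambda must be non-negative", call. = FALSE)
  }

  intercept_only <- function() {
    mu <- wmean(y)
    .nuisance_fit(target, character(0), Inf,
                  coef_lasso = c(`(Intercept)` = mu), coef_post = NULL,
                  fitted_new = if (!is.null(z_new)) rep(mu, nrow(z_new)),
                  n_train = n)
  }
  if (p == 0L || rule == "inf" || stats::var(y) == 0) return(intercept_only())

  ols_all <- function(cols) {
    X <- cbind(`(Intercept)` = 1, z_eff[, cols, drop = FALSE])
    qf <- qr(X * sqrt(weights))
    if (qf$rank < ncol(X)) return(NULL)
    co <- qr.coef(qf, y * sqrt(weights))
    fitted_new <- if (!is.null(z_new)) {
      drop(cbind(1, z_new[, cols, drop = FALSE]) %*% co)
    }
    list(coef = co, fitted_new = fitted_new)
  }

  if (rule == "fixed" && lam == 0) {
    fit <- ols_all(colnames(z_eff))
    if (is.null(fit)) stop("zero-penalty fit is rank deficient", call. = FALSE)
    return(.nuisance_fit(target, colnames(z_eff), 0, fit$coef, fit$coef,
                         fit$fitted_new, n))
  }

  if (rule == "plugin") {
    sigma <- sqrt(sum(weights * (y - wmean(y))^2) / sum(weights))
    lam <- .plugin_lambda(sigma, n, p)
  }

  if (p == 1L) {
    # glmnet needs >= 2 columns; solve the single standardized coordinate
    # in closed form (soft threshold)
    x1 <- z_eff[, 1]
    wn <- weights / mean(weights)
    mx <- mean(wn * x1); sx <- sqrt(mean(wn * (x1 - mx)^2))
    my <- mean(wn * y)
    if (rule == "cv") {  # no path to cross-validate; use plugin level
      sigma <- sqrt(mean(wn * (y - my)^2))
      lam <- .plugin_lambda(sigma, n, 1L)
    }
    xs <- (x1 - mx) / sx
    b_std <- mean(wn * xs * (y - my))
    b_std <- sign(b_std) * max(abs(b_std) - lam, 0)
    b1 <- b_std / sx
    sel <- if (b1 != 0) colnames(z_eff) else character(0)
    coef_lasso <- stats::setNames(c(my - b1 * mx, b1),
                                  c("(Intercept)", colnames(z_eff)))
  } else {
    if (rule == "cv") {
      cvfit <- glmnet::cv.glmnet(z_eff, y, weights = weights,
                                 foldid = .cv_foldid(n), standardize = TRUE)
      lam <- cvfit$lambda.min
      gfit <- cvfit$glmnet.fit
    } else {
      # short warm-start path ending exactly at the requested lambda
      gfit <- glmnet::glmnet(z_eff, y, weights = weights, standardize = TRUE,
                             lambda = lam * 2^(6:0), thresh = 1e-10)
    }
    co <- as.matrix(glmnet::coef.glmnet(gfit, s = lam))
    sel <- rownames(co)[-1][co[-1, 1] != 0]
    coef_lasso <- stats::setNames(co[, 1], rownames(co))
  }

  coef_post <- NULL
  fitted_new <- NULL
  if (post) {
    refit <- if (length(sel)) ols_all(sel) else NULL
    if (length(sel) == 0L) {
      mu <- wmean(y)
      coef_post <- c(`(Intercept)` = mu)
      fitted_new <- if (!is.null(z_new)) rep(mu, nrow(z_new))
    } else if (!is.null(refit)) {
      coef_post <- refit$coef
      fitted_new <- refit$fitted_new
    }
  }
  if (is.null(fitted_new) && !is.null(z_new)) {
    # penalized predictions (post refit disabled or rank deficient)
    b <- coef_lasso[-1]
    fitted_new <- drop(z_new[, names(b), drop = FALSE] %*% b) + coef_lasso[1]
  }
  .nuisance_fit(target, sel, lam, coef_lasso, coef_post, fitted_new, n)
}

#' LASSO logistic nuisance fit with unpenalized treatment columns
#'
#' Fits an l1-penalized logistic regression of a binary target on the
#' controls, optionally keeping listed columns (the treatments) exempt from
#' the penalty, then refits an unpenalized logit on the selected columns for
#' prediction. Returns, alongside the fit, the control-only part of the
#' linear index evaluated on new records (the estimated g(Z) used by the
#' orthogonal score) and the coefficients on the unpenalized columns.
#'
#' @inheritParams lasso_linear
#' @param y binary 0/1 target; both classes must be present.
#' @param unpen optional numeric matrix of unpenalized columns (same rows as
#'   `z`), e.g. the treatments.
#' @param unpen_new optional matrix matching `unpen` for the new records.
#' @param lambda `"cv"`, `"plugin"` (with sigma_hat = sqrt(pbar(1-pbar))), or
#'   a fixed value; `Inf` penalizes all of `z` away.
#' @return object of class `nuisance_fit` with additionally `beta_unpen`
#'   (coefficients on `unpen`), `g_new` (intercept + control part of the
#'   index at `z_new`) and `prob_new` (fitted probabilities at
#'   `(unpen_new, z_new)` when `unpen_new` is supplied).
#' @export
lasso_logit <- function(z, y, z_new = NULL, lambda = "plugin", unpen = NULL,
                        unpen_new = NULL, target = "y", post = TRUE) {
  n <- length(y)
  if (!all(y %in% c(0, 1))) stop("target must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training fold contains a single outcome class; ",
         "use folds stratified by the outcome (make_folds(stratify = y))",
         call. = FALSE)
  }
  if (!is.null(z)) z <- as.matrix(z)
  if (!is.null(unpen)) unpen <- as.matrix(unpen)
  z_eff <- .drop_constant(z)
  p <- if (is.null(z_eff)) 0L else ncol(z_eff)
  q <- if (is.null(unpen)) 0L else ncol(unpen)

  lam <- NA_real_
  if (is.character(lambda)) {
    rule <- match.arg(lambda, c("cv", "plugin"))
  } else {
    rule <- "fixed"; lam <- as.numeric(lambda)
    if (!is.finite(lam) && lam > 0) rule <- "inf"
  }
  if (rule == "plugin") {
    pbar <- mean(y)
    lam <- .plugin_lambda(sqrt(pbar * (1 - pbar)), n, max(p, 1L))
  }

  # unpenalized logit on (intercept, unpen, cols) via IRLS
  refit_logit <- function(cols) {
    X <- cbind(`(Intercept)` = rep(1, n),
               if (q) unpen,
               if (length(cols)) z_eff[, cols, drop = FALSE])
    if (qr(X)$rank < ncol(X)) return(NULL)
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
    if (!fit$converged) return(NULL)
    stats::setNames(fit$coefficients, colnames(X))
  }

  sel <- character(0)
  coef_lasso <- NULL
  if (p == 0L || rule == "inf") {
    co <- refit_logit(character(0))
    if (is.null(co)) stop("degenerate logit refit failed", call. = FALSE)
    coef_lasso <- co
  } else {
    X <- cbind(if (q) unpen, z_eff)
    pf <- c(rep(0, q), rep(1, p))
    if (rule == "cv") {
      cvfit <- glmnet::cv.glmnet(X, y, family = "binomial",
                                 penalty.factor = pf,
                                 foldid = .cv_foldid(n),
                                 standardize = TRUE)
      lam <- cvfit$lambda.min
      gfit <- cvfit$glmnet.fit
    } else {
      gfit <- glmnet::glmnet(X, y, family = "binomial", penalty.factor = pf,
                             standardize = TRUE, lambda = lam * 2^(6:0),
                             thresh = 1e-10)
    }
    co <- as.matrix(glmnet::coef.glmnet(gfit, s = lam))
    coef_lasso <- stats::setNames(co[, 1], rownames(co))
    zpart <- coef_lasso[seq.int(2L + q, length.out = p)]
    sel <- names(zpart)[zpart != 0]
  }

  coef_post <- NULL
  if (post) coef_post <- refit_logit(sel)
  co_use <- if (!is.null(coef_post)) coef_post else coef_lasso

  un_names <- if (q) colnames(unpen) else character(0)
  beta_unpen <- if (q) co_use[un_names] else numeric(0)
  g_at <- function(znew) {
    g <- rep(co_use[["(Intercept)"]], nrow(znew))
    zc <- intersect(names(co_use), colnames(znew))
    zc <- zc[co_use[zc] != 0]
    if (length(zc)) g <- g + drop(znew[, zc, drop = FALSE] %*% co_use[zc])
    g
  }
  g_new <- NULL; prob_new <- NULL
  if (!is.null(z_new)) {
    g_new <- g_at(as.matrix(z_new))
    if (q && !is.null(unpen_new)) {
      eta <- g_new + drop(as.matrix(unpen_new) %*% beta_unpen)
      prob_new <- stats::plogis(eta)
    }
  }
  out <- .nuisance_fit(target, sel, lam, coef_lasso, coef_post,
                       fitted_new = prob_new, n_train = n)
  out$beta_unpen <- beta_unpen
  out$g_new <- g_new
  out$prob_new <- prob_new
  out
}

.nuisance_fit <- function(target, selected, lambda, coef_lasso, coef_post,
                          fitted_new, n_train) {
  structure(list(target = target, selected = selected, lambda = lambda,
                 coef_lasso = coef_lasso, coef_post = coef_post,
                 fitted_new = fitted_new, n_train = n_train),
            class = "nuisance_fit")
}

#' @export
print.nuisance_fit <- function(x, ...) {
  cat(sprintf("nuisance fit for %s: %d controls selected (lambda = %.4g)\n",
              x$target, length(x$selected), x$lambda))
  invisible(x)
}
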