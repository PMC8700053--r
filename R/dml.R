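# Cross-fit partialling-out estimation of the partially linear model and its
# logistic analogue. Nuisance functions (outcome-on-controls and
# treatment-on-controls) are fitted on K-1 training folds, predicted on the
# held-out fold, and the treatment effects are recovered from the held-out
# residuals; repeating over R independent splits and averaging absorbs the
# variability introduced by data-driven control selection.

.as_treatment_matrix <- function(d) {
  if (is.null(dim(d))) d <- matrix(d, ncol = 1L, dimnames = list(NULL, "d"))
  d <- as.matrix(d)
  if (is.null(colnames(d))) colnames(d) <- paste0("d", seq_len(ncol(d)))
  if (!ncol(d) %in% 1:2) stop("expected 1 or 2 treatment columns", call. = FALSE)
  d
}

.as_control_matrix <- function(z, n) {
  if (is.null(z)) return(matrix(numeric(0), nrow = n, ncol = 0L))
  z <- as.matrix(z)
  if (is.null(colnames(z)) && ncol(z)) colnames(z) <- paste0("z", seq_len(ncol(z)))
  z
}

.fold_indices <- function(plan, r) {
  lab <- plan$assign[, r]
  lapply(seq_len(plan$K), function(k) {
    test <- which(lab == k)
    train <- if (plan$K == 1L) test else which(lab != k)
    list(train = train, test = test)
  })
}

#' Cross-fit partialling-out for the partially linear model
#'
#' Estimates treatment effects beta in `Y = D beta + f(Z) + e` with
#' high-dimensional controls Z. For each repetition of the fold plan, LASSO
#' nuisance regressions of Y and of each treatment on Z are fitted on the
#' training folds and predicted out of fold; the pooled held-out residuals of
#' Y are then regressed on the residualized treatments (with an intercept,
#' reported as a diagnostic) with an HC1 sandwich variance. Per-repetition
#' estimates are combined by [aggregate_resamples()].
#'
#' @param y continuous outcome vector.
#' @param d treatment vector or matrix (1 or 2 columns).
#' @param z control matrix (may have more columns than rows, or be NULL).
#' @param plan a [make_folds()] plan for `length(y)` records.
#' @param lambda penalty rule passed to [lasso_linear()].
#' @param post use post-LASSO refits for nuisance predictions.
#' @return an `estimation_result` (method `"dml"`, family `"linear"`) with
#'   extras: `per_rep` (per-repetition estimates and variances), `selection`
#'   (controls selected per nuisance per repetition), `n_lasso_fits` per
#'   nuisance, `intercept` diagnostic, and the fold plan metadata.
#' @export
crossfit_plm <- function(y, d, z = NULL, plan = make_folds(length(y)),
                         lambda = "cv", post = TRUE) {
  d <- .as_treatment_matrix(d)
  n <- length(y)
  z <- .as_control_matrix(z, n)
  stopifnot(nrow(d) == n, nrow(z) == n, plan$n == n)
  q <- ncol(d)
  nuis <- c("Y", colnames(d))

  est <- matrix(NA_real_, plan$R, q, dimnames = list(NULL, colnames(d)))
  vcovs <- vector("list", plan$R)
  intercepts <- numeric(plan$R)
  sel_count <- array(0L, dim = c(plan$R, length(nuis)),
                     dimnames = list(NULL, nuis))
  sel_union <- stats::setNames(
    rep(list(vector("list", plan$R)), length(nuis)), nuis)

  for (r in seq_len(plan$R)) {
    yhat <- rep(NA_real_, n)
    dhat <- matrix(NA_real_, n, q)
    sel_r <- stats::setNames(rep(list(character(0)), length(nuis)), nuis)
    for (fold in .fold_indices(plan, r)) {
      tr <- fold$train; te <- fold$test
      fy <- lasso_linear(z[tr, , drop = FALSE], y[tr],
                         z_new = z[te, , drop = FALSE],
                         lambda = lambda, target = "Y", post = post)
      yhat[te] <- fy$fitted_new
      sel_r[["Y"]] <- union(sel_r[["Y"]], fy$selected)
      sel_count[r, "Y"] <- sel_count[r, "Y"] + length(fy$selected)
      for (j in seq_len(q)) {
        fj <- lasso_linear(z[tr, , drop = FALSE], d[tr, j],
                           z_new = z[te, , drop = FALSE],
                           lambda = lambda, target = nuis[j + 1L], post = post)
        dhat[te, j] <- fj$fitted_new
        sel_r[[nuis[j + 1L]]] <- union(sel_r[[nuis[j + 1L]]], fj$selected)
        sel_count[r, nuis[j + 1L]] <- sel_count[r, nuis[j + 1L]] +
          length(fj$selected)
      }
    }
    ytil <- y - yhat
    dtil <- d - dhat
    for (j in seq_len(q)) {
      if (stats::var(dtil[, j]) <=
            1e-10 * max(stats::var(d[, j]), .Machine$double.eps)) {
        stop(sprintf(
          "treatment '%s' is not identified: residualized variance is ",
          colnames(d)[j]), "numerically zero after partialling out controls",
          call. = FALSE)
      }
    }
    X <- cbind(`(Intercept)` = 1, dtil)
    fit <- stats::lm.fit(X, ytil)
    V <- .hc1_lm(X, fit$residuals)
    est[r, ] <- fit$coefficients[-1]
    vcovs[[r]] <- V[-1, -1, drop = FALSE]
    intercepts[r] <- fit$coefficients[1]
    for (nm in nuis) sel_union[[nm]][[r]] <- sel_r[[nm]]
  }

  agg <- aggregate_resamples(est, vcovs)
  res <- .estimation_result(
    est = agg$estimate, se = sqrt(diag(agg$vcov)),
    treatments = colnames(d), family = "linear", n = n, method = "dml",
    extra = list(
      vcov = agg$vcov,
      per_rep = list(estimates = est, vcovs = vcovs, intercepts = intercepts),
      selection = list(count = sel_count, selected = sel_union),
      n_lasso_fits = stats::setNames(rep(plan$K * plan$R, length(nuis)), nuis),
      plan = plan[c("n", "K", "R", "seed", "stratified")],
      lambda_rule = if (is.character(lambda)) lambda else "fixed"))
  res
}

#' Cross-fit partialling-out for binary outcomes (logistic model)
#'
#' Estimates treatment log-odds beta in `P(Y=1|D,Z) = plogis(D beta + g(Z))`.
#' On the training folds, an l1-penalized logit of Y on (D, Z) with
#' unpenalized treatments yields the control index g(Z) and a preliminary
#' beta; each treatment is then regressed on Z by weighted LASSO with the
#' logistic information weights. On the held-out folds the Neyman-orthogonal
#' score `(Y - plogis(D beta + g(Z))) * (D - m(Z))` is accumulated and the
#' pooled moment condition is solved for beta by damped Newton iteration,
#' with a sandwich variance from the score outer products. Per-repetition
#' estimates are aggregated as in the linear engine; `exp(beta)` is reported
#' as an odds ratio.
#'
#' @inheritParams crossfit_plm
#' @param y binary 0/1 outcome; the fold plan should be stratified by `y`.
#' @param lambda penalty rule for both the logit selection step and the
#'   weighted linear treatment regressions.
#' @return an `estimation_result` (method `"dml"`, family `"logit"`) with the
#'   same extras as [crossfit_plm()].
#' @export
crossfit_logit <- function(y, d, z = NULL, plan = make_folds(length(y)),
                           lambda = "plugin", post = TRUE) {
  d <- .as_treatment_matrix(d)
  n <- length(y)
  z <- .as_control_matrix(z, n)
  stopifnot(nrow(d) == n, nrow(z) == n, plan$n == n)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  q <- ncol(d)
  nuis <- c("Y", colnames(d))

  est <- matrix(NA_real_, plan$R, q, dimnames = list(NULL, colnames(d)))
  vcovs <- vector("list", plan$R)
  sel_count <- array(0L, dim = c(plan$R, length(nuis)),
                     dimnames = list(NULL, nuis))
  sel_union <- stats::setNames(
    rep(list(vector("list", plan$R)), length(nuis)), nuis)

  for (r in seq_len(plan$R)) {
    ghat <- rep(NA_real_, n)
    mhat <- matrix(NA_real_, n, q)
    beta0 <- matrix(NA_real_, plan$K, q)
    sel_r <- stats::setNames(rep(list(character(0)), length(nuis)), nuis)
    k <- 0L
    for (fold in .fold_indices(plan, r)) {
      k <- k + 1L
      tr <- fold$train; te <- fold$test
      fy <- lasso_logit(z[tr, , drop = FALSE], y[tr],
                        z_new = z[te, , drop = FALSE],
                        unpen = d[tr, , drop = FALSE],
                        lambda = lambda, target = "Y", post = post)
      ghat[te] <- fy$g_new
      beta0[k, ] <- fy$beta_unpen
      sel_r[["Y"]] <- union(sel_r[["Y"]], fy$selected)
      sel_count[r, "Y"] <- sel_count[r, "Y"] + length(fy$selected)
      # logistic information weights at the training-fold fit
      co <- if (!is.null(fy$coef_post)) fy$coef_post else fy$coef_lasso
      eta_tr <- rep(co[["(Intercept)"]], length(tr)) +
        drop(d[tr, , drop = FALSE] %*% fy$beta_unpen)
      zc <- intersect(names(co), colnames(z))
      zc <- zc[co[zc] != 0]
      if (length(zc)) {
        eta_tr <- eta_tr + drop(z[tr, zc, drop = FALSE] %*% co[zc])
      }
      w_tr <- stats::plogis(eta_tr) * (1 - stats::plogis(eta_tr))
      w_tr <- pmax(w_tr, 1e-6)
      for (j in seq_len(q)) {
        fj <- lasso_linear(z[tr, , drop = FALSE], d[tr, j],
                           z_new = z[te, , drop = FALSE],
                           lambda = lambda, weights = w_tr,
                           target = nuis[j + 1L], post = post)
        mhat[te, j] <- fj$fitted_new
        sel_r[[nuis[j + 1L]]] <- union(sel_r[[nuis[j + 1L]]], fj$selected)
        sel_count[r, nuis[j + 1L]] <- sel_count[r, nuis[j + 1L]] +
          length(fj$selected)
      }
    }
    dres <- d - mhat
    sol <- .solve_orthogonal_logit(y, d, dres, ghat, beta_start = colMeans(beta0))
    est[r, ] <- sol$beta
    vcovs[[r]] <- sol$vcov
    for (nm in nuis) sel_union[[nm]][[r]] <- sel_r[[nm]]
  }

  agg <- aggregate_resamples(est, vcovs)
  .estimation_result(
    est = agg$estimate, se = sqrt(diag(agg$vcov)),
    treatments = colnames(d), family = "logit", n = n, method = "dml",
    extra = list(
      vcov = agg$vcov,
      per_rep = list(estimates = est, vcovs = vcovs),
      selection = list(count = sel_count, selected = sel_union),
      n_lasso_fits = stats::setNames(rep(plan$K * plan$R, length(nuis)), nuis),
      plan = plan[c("n", "K", "R", "seed", "stratified")],
      lambda_rule = if (is.character(lambda)) lambda else "fixed"))
}

# Solve the pooled orthogonal moment condition
#   mean_i (y_i - plogis(d_i' beta + g_i)) * (d_i - m_i) = 0
# by damped Newton with the analytic Jacobian; returns beta and the sandwich
# variance J^-1 S J^-T / n.
.solve_orthogonal_logit <- function(y, d, dres, g, beta_start,
                                    tol = 1e-10, maxit = 50L) {
  n <- length(y)
  q <- ncol(d)
  score_bar <- function(beta) {
    p <- stats::plogis(drop(d %*% beta) + g)
    colMeans(dres * (y - p))
  }
  jac <- function(beta) {
    eta <- drop(d %*% beta) + g
    w <- stats::plogis(eta) * (1 - stats::plogis(eta))
    -crossprod(dres * w, d) / n
  }
  beta <- beta_start
  if (any(!is.finite(beta))) beta <- rep(0, q)
  s <- score_bar(beta)
  for (it in seq_len(maxit)) {
    if (sqrt(sum(s^2)) < tol) break
    J <- jac(beta)
    step <- tryCatch(solve(J, s), error = function(e) NULL)
    if (is.null(step)) {
      stop("orthogonal-score Jacobian is singular; score norm = ",
           format(sqrt(sum(s^2))), call. = FALSE)
    }
    # damped update: halve until the score norm does not increase
    lam <- 1
    repeat {
      cand <- beta - lam * step
      s_cand <- score_bar(cand)
      if (sqrt(sum(s_cand^2)) <= sqrt(sum(s^2)) || lam < 1e-6) break
      lam <- lam / 2
    }
    beta <- cand; s <- s_cand
  }
  if (sqrt(sum(s^2)) >= max(tol, 1e-8)) {
    stop("orthogonal-score root finding did not converge: score norm = ",
         format(sqrt(sum(s^2))), " after ", maxit, " iterations",
         call. = FALSE)
  }
  p <- stats::plogis(drop(d %*% beta) + g)
  psi <- dres * (y - p)
  S <- crossprod(psi) / n
  J <- jac(beta)
  Jinv <- solve(J)
  V <- Jinv %*% S %*% t(Jinv) / n
  list(beta = stats::setNames(beta, colnames(d)), vcov = V,
       score_norm = sqrt(sum(s^2)), iterations = it)
}

#' Aggregate estimates over repeated sample splits
#'
#' The point estimate is the mean of the per-repetition estimates; the
#' variance is the mean of the per-repetition variances plus the dispersion
#' of the estimates around their mean,
#' `mean_r(V_r + (b_r - b_bar)(b_r - b_bar)')`, so that the extra variability
#' introduced by random splitting and repeated selection widens the reported
#' standard errors. With R = 1 the inputs are returned unchanged.
#'
#' @param estimates numeric matrix R x q (or length-R vector for q = 1) of
#'   per-repetition estimates.
#' @param variances list of R q x q covariance matrices (or length-R vector
#'   of variances for q = 1).
#' @return list with `estimate` (length q) and `vcov` (q x q).
#' @examples
#' aggregate_resamples(c(1, 3), c(0.5, 0.5))  # estimate 2, variance 1.5
#' @export
aggregate_resamples <- function(estimates, variances) {
  if (is.null(dim(estimates))) estimates <- matrix(estimates, ncol = 1L)
  R <- nrow(estimates); q <- ncol(estimates)
  if (!is.list(variances)) {
    if (q != 1L) stop("supply variances as a list of q x q matrices", call. = FALSE)
    variances <- lapply(variances, function(v) matrix(v, 1L, 1L))
  }
  if (length(variances) != R) stop("need one variance per repetition", call. = FALSE)
  bbar <- colMeans(estimates)
  V <- matrix(0, q, q)
  for (r in seq_len(R)) {
    delta <- estimates[r, ] - bbar
    V <- V + as.matrix(variances[[r]]) + tcrossprod(delta)
  }
  V <- V / R
  list(estimate = stats::setNames(bbar, colnames(estimates)), vcov = V)
}
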