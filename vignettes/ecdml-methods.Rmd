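---
title: "Methods: cross-fit partialling-out for ECD analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-fit partialling-out for ECD analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ecdml)
```

## The estimation problem

The package contrasts two ways of estimating how child stature (HAZ or a
stunting flag, $D_1$) and maternal education in years ($D_2$) relate to
early childhood development outcomes $Y$ in cross-sectional survey data.

The **ad-hoc benchmark** is the conventional regression
$Y = \beta_1 D_1 + \beta_2 D_2 + \varphi X + \epsilon$ with a small,
fixed control set $X$ (child sex, age and age squared, household size,
dependency ratios, wealth-quintile dummies, rural flag, region dummies).
Its coefficients are partial correlations; they carry a causal reading
only if the treatments are as good as randomly assigned given $X$, which
a handful of controls rarely justifies.

The **DML arm** works with the partially linear model
$$Y = \beta_1 D_1 + \beta_2 D_2 + f(Z) + \epsilon, \qquad
  D_1 = g(Z) + v_1, \qquad D_2 = h(Z) + v_2,$$
where $Z$ is a high-dimensional control vector (hundreds of columns,
possibly more than observations). Cross-fit partialling-out estimates
$f, g, h$ by LASSO with a post-selection refit on $K-1$ training folds,
predicts them on the held-out fold, and regresses the pooled held-out
residuals $\tilde Y$ on $(\tilde D_1, \tilde D_2)$. Sample splitting
removes the own-observation overfitting bias; the Neyman orthogonality of
the residual-on-residual moment makes the estimate first-order
insensitive to nuisance estimation error. The random $K$-fold split is
repeated $R$ times; point estimates are averaged and the reported
variance is $\frac{1}{R}\sum_r \{V_r + (\hat\beta_r - \bar\beta)^2\}$, so
the variability introduced by data-driven selection widens the standard
errors rather than disappearing. With the defaults $K = 10$, $R = 5$,
each nuisance function is fitted 50 times.

For binary outcomes the engine uses the orthogonal-score logistic
analogue: on the training folds an $\ell_1$-penalized logit of $Y$ on
$(D, Z)$ — treatments unpenalized — gives the control index $\hat g(Z)$
and a preliminary $\tilde\beta$; each treatment is regressed on $Z$ by
LASSO weighted with the logistic information
$\Lambda'(D\tilde\beta + \hat g(Z))$ to give $\hat m(Z)$; on the held-out
folds the score $\{Y - \Lambda(D\beta + \hat g(Z))\}\,(D - \hat m(Z))$
is accumulated and solved for $\beta$ by damped Newton iteration, with a
sandwich variance from the score outer products. Treatment effects are
reported as odds ratios $e^{\hat\beta}$. The exact internals of the
survey-software implementation this mirrors are not published; the score
construction here follows the partialling-out logit of the
high-dimensional-inference literature and is validated against its exact
degenerate reductions (with no controls and a single split it reproduces
the plain logit MLE; the linear engine reproduces full-sample OLS by the
Frisch–Waugh–Lovell identity when the penalty is forced to zero).

## Tunable parameters

* `K` (default 10) and `R` (default 5): folds and repetitions. `K = 1`
  is a degenerate no-splitting mode kept for exact oracle comparisons —
  training and prediction then use the same records, so it must not be
  used for inference.
* `lambda`: penalty rule for the nuisance LASSOs. `"cv"` (default in
  `crossfit_plm`) minimizes 10-fold cross-validated prediction error
  within each training fold; `"plugin"` uses
  $1.1\,\hat\sigma\,\Phi^{-1}(1 - 0.1/2p)/\sqrt n$ on glmnet's
  per-observation scale, the standard self-normalized rate. Plugin is
  used for the repeated simulation studies because it is one coordinate
  descent pass instead of eleven; both rules are exposed everywhere. A
  fixed numeric value (including 0 and `Inf`) is accepted for oracle
  tests.
* Post-LASSO refit (`post = TRUE`): nuisance predictions come from an
  unpenalized refit on the selected columns, which matches
  partialling-out semantics and reduces shrinkage bias in the residuals;
  the penalized fit is used automatically if the refit is rank deficient.
* `n_floor` (default 200): minimum cell size in the comparison grids;
  smaller cells are marked `insufficient_n` rather than fitted.
* Smoother: Epanechnikov kernel, degree-0 local mean, rule-of-thumb
  bandwidth $2.34\,\mathrm{sd}(\mathrm{age})\,n^{-1/5}$ months, all
  overridable. Degree 0 is the default of the smoothing command the
  growth-faltering literature uses.

## Numerical and design choices

* **Stunting boundary.** The operational definition is HAZ $\le -2$
  (the constructive table definition); a `strict = TRUE` switch gives
  the HAZ $< -2$ variant found in running text.
* **Item-domain layout.** 3 literacy + 2 physical + 2 learning + 3
  socio-emotional items, the layout implied by the scoring criteria
  (at least 2 of 3; any of 2; any of 2; 2 of 3).
* **ECDI standardization** uses the sample ($n-1$) standard deviation,
  the convention of survey software z-scoring; the choice is recorded in
  the output's `sd_type` attribute. Zero variance is an error, never a
  silent NaN. Missing items make the affected domain flag, composite and
  total missing (complete-case; no imputation).
* **Standard errors.** HC1 sandwich throughout the ad-hoc arm (the
  prevailing convention for survey microdata); the DML final stages use
  their own sandwich forms. Survey weights and cluster designs are out
  of scope. p-values are two-sided normal.
* **Determinism.** Fold plans are reproducible from `(n, K, R, seed)`;
  internal cross-validation folds are assigned systematically over
  training rows instead of randomly, which makes estimates exactly
  invariant to fold relabeling and reproducible without hidden RNG
  state. Generator output is byte-identical across runs for a fixed
  config.
* **Stratification.** Folds for binary outcomes are stratified by the
  outcome so every training fold contains both classes; an unstratified
  single-class fold is an error with advice, not a warning.
* **Convergence.** Logit fits iterate to a relative tolerance of 1e-10
  with at most 100 IRLS iterations; the orthogonal-score Newton solver
  uses step halving and requires a score norm below 1e-8 — failures are
  errors carrying diagnostics. Collinear ad-hoc controls are dropped by
  pivoted QR and reported; a collinear treatment is an error.

## What the generator emulates — and what it does not

`simulate_ecd()` reproduces the features the estimator is sensitive to:
sparse high-dimensional confounding (shared supports between $f$, $g$,
$h$ with positive wealth-like signs, scaled by `confounding`), two
correlated treatments, continuous and binary outcomes with known
coefficients, a zero-inflated integer education distribution (rural/urban
means 3.27/8.32, rounded and censored to 0–18 years), a quadratic HAZ
age curve calibrated so the 36–59-month mean is −1.87 with a
population-mean-preserving rural gap of 0.77, and item responses whose
domain intercepts are root-found so expected on-track shares hit the
configured targets (0.30, 0.92, 0.79, 0.72) on the supplied latent
sample. The latent score feeding the items is the standardized
continuous outcome — a modeling convenience, not a measurement claim.

Deliberate simplifications: asset indicators are independent Bernoulli
draws, independent of rurality except through the explicit interaction
columns; ages are uniform; there is no survey clustering, no missingness
outside the under-36 item module, and no measurement error in the
z-scores. Passing tests therefore demonstrate correctness of the
machinery under the assumed model, not robustness to the messiness of
real survey data.

The closed-form omitted-variable-bias oracle
(`analytic_naive_bias()`) is exact for the continuous-education variant
(`edu_integer = FALSE`, `d1_type = "haz"`, regime `"plm"`), where the
confounding supports are independent of the ad-hoc set by construction
and all second moments follow from the Bernoulli prevalences; rounding
and censoring of education perturb second moments slightly, so the
integer variant is checked stochastically instead.

## Problem sizes used in the simulation studies

The shipped studies use: the survey-scale scenario $n = 10000$,
$p = 451$ for the worked example and the acceptance script; the
confounded recovery scenario $n = 4000$, $p = 200$, $s = 10$ with
$(\beta_1, \beta_2) = (-0.2, 0.02)$ over 100 Monte-Carlo replicates
($K = 5$, $R = 1$, plugin penalty); the logistic size study $n = 2000$,
$p = 100$ over 200 replicates; and the logistic coverage study
$n = 6000$, $p = 200$ with a true education odds ratio of 1.03 over 100
replicates. These sizes keep each study informative about the target
regime while running comfortably on a single CPU.

## Known limitations

The aggregation across repeated splits uses the mean with a
dispersion-augmented variance; median aggregation (more robust to an
occasional wild split) is not implemented. The logit engine assumes the
binary outcome truly follows the logistic partially linear index — for
derived outcomes such as stunting (a thresholded continuous variable) it
is a working approximation. Instrumental-variable variants, survey
weights, cluster-robust variances and WHO growth-standard z-score
construction are out of scope: z-scores enter as data.
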