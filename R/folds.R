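#' Build a K-fold, R-repetition sample-splitting plan
#'
#' Cross-fit partialling-out estimates nuisance functions on K-1 folds and
#' predicts on the held-out fold; repeating the random split R times and
#' averaging accounts for the extra variability that data-driven selection
#' introduces. With K = 10 and R = 5 each nuisance function is fitted
#' 50 times. The plan is fully reproducible from `(n, K, R, seed)`.
#'
#' @param n number of records.
#' @param K number of folds (1 <= K <= n; `K = 1` is a degenerate
#'   no-splitting mode where training and prediction use the full sample,
#'   provided for exact oracle comparisons).
#' @param R number of repetitions (>= 1).
#' @param seed integer master seed.
#' @param stratify optional vector of length `n` (e.g. a binary outcome);
#'   folds are then balanced within each stratum so every training set
#'   contains all classes.
#' @return an object of class `fold_plan`: list with `n`, `K`, `R`, `seed`,
#'   and `assign`, an `n x R` integer matrix of fold labels in `1..K`.
#' @export
make_folds <- function(n, K = 10L, R = 5L, seed = 1L, stratify = NULL) {
  n <- as.integer(n); K <- as.integer(K); R <- as.integer(R)
  if (K > n) stop("K must not exceed n", call. = FALSE)
  if (K < 1L || R < 1L || n < 1L) stop("n, K, R must be positive", call. = FALSE)
  if (!is.null(stratify) && length(stratify) != n) {
    stop("stratify must have length n", call. = FALSE)
  }
  assign <- matrix(NA_integer_, n, R)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  for (r in seq_len(R)) {
    if (is.null(stratify)) {
      assign[, r] <- sample(rep_len(seq_len(K), n))
    } else {
      for (g in split(seq_len(n), stratify)) {
        assign[g, r] <- sample(rep_len(seq_len(K), length(g)))
      }
    }
  }
  structure(list(n = n, K = K, R = R, seed = as.integer(seed),
                 stratified = !is.null(stratify), assign = assign),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold plan: n = %d, K = %d, R = %d, seed = %d%s\n",
              x$n, x$K, x$R, x$seed,
              if (x$stratified) " (stratified)" else ""))
  invisible(x)
}

# save/restore the global RNG state so plan construction does not perturb
# the caller's random stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
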