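#' ECD item-to-domain layout
#'
#' The MICS child-development module asks ten yes/no questions about children
#' aged 36--59 months, grouped into four developmental domains:
#' literacy/numeracy (3 items), physical (2), learning (2) and
#' socio-emotional (3). This constant records the layout used throughout the
#' package; item matrices are expected to supply columns in this order.
#'
#' @format Named list mapping domain name to number of items.
#' @export
ecd_domains <- list(
  literacy = 3L,
  physical = 2L,
  learning = 2L,
  socioemotional = 3L
)

# minimum count of positive responses for a domain to be "on track"
.domain_threshold <- c(
  literacy = 2L,        # at least two of the three
  physical = 1L,        # either item
  learning = 1L,        # one or both
  socioemotional = 2L   # two of the three
)

#' Score one developmental domain
#'
#' Applies the domain's on-track rule to its binary item responses:
#' literacy/numeracy requires at least 2 of 3 positive responses, physical
#' development at least 1 of 2, learning at least 1 of 2, and socio-emotional
#' development at least 2 of 3. Children with any missing response in the
#' domain get a missing flag (no imputation).
#'
#' @param responses numeric matrix (or vector for a single child) of 0/1
#'   responses, one row per child, with the domain's number of columns.
#' @param domain one of `"literacy"`, `"physical"`, `"learning"`,
#'   `"socioemotional"`.
#' @return integer vector of 0/1 on-track flags (NA where any item missing).
#' @examples
#' score_domain(c(1, 1, 0), "literacy")        # on track
#' score_domain(c(0, 0), "physical")           # not on track
#' score_domain(rbind(c(1, 0, 1), c(0, 0, 1)), "socioemotional")
#' @export
score_domain <- function(responses, domain) {
  domain <- match.arg(domain, names(ecd_domains))
  k <- ecd_domains[[domain]]
  if (is.null(dim(responses))) responses <- matrix(responses, nrow = 1L)
  responses <- as.matrix(responses)
  if (ncol(responses) != k) {
    stop(sprintf("domain '%s' expects %d item columns, got %d",
                 domain, k, ncol(responses)), call. = FALSE)
  }
  bad <- responses[!is.na(responses)]
  if (length(bad) && !all(bad %in% c(0, 1))) {
    stop("item responses must be 0/1 or NA", call. = FALSE)
  }
  pos <- rowSums(responses)          # NA propagates if any item missing
  as.integer(pos >= .domain_threshold[[domain]])
}

#' UNICEF composite on-track indicator
#'
#' A child is developmentally on track (UNICEF ECD indicator) if on track in
#' at least 3 of the 4 domains. Any missing domain flag yields a missing
#' composite.
#'
#' @param domain_flags numeric matrix with 4 columns of 0/1 domain flags (or a
#'   length-4 vector for one child).
#' @return integer vector of 0/1 (NA if any flag missing).
#' @examples
#' unicef_composite(c(1, 1, 1, 0))  # 1
#' unicef_composite(c(1, 1, 0, 0))  # 0
#' @export
unicef_composite <- function(domain_flags) {
  if (is.null(dim(domain_flags))) domain_flags <- matrix(domain_flags, nrow = 1L)
  domain_flags <- as.matrix(domain_flags)
  if (ncol(domain_flags) != 4L) {
    stop("expected 4 domain flags per child", call. = FALSE)
  }
  as.integer(rowSums(domain_flags) >= 3L)
}

#' Total ECD score and standardized index (ECDI)
#'
#' The total score is the number of positive responses over all ten items,
#' ignoring domains. The ECDI is its z-score over the supplied sample:
#' (total - mean) / SD, using the sample (n-1) standard deviation. Children
#' with any missing item have missing total and ECDI; they are excluded from
#' the standardization moments.
#'
#' @param items numeric matrix with 10 columns of 0/1 item responses, one row
#'   per child.
#' @return list with `total_score` (integer, 0--10) and `ecdi_z` (numeric).
#' @export
total_and_standardize <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) != 10L) stop("expected 10 item columns", call. = FALSE)
  total <- rowSums(items)
  ok <- !is.na(total)
  if (sum(ok) < 2L) {
    stop("need at least 2 children with complete items to standardize",
         call. = FALSE)
  }
  s <- stats::sd(total[ok])
  if (s == 0) {
    stop("zero variance of total scores: ECDI standardization undefined",
         call. = FALSE)
  }
  list(total_score = as.integer(total),
       ecdi_z = (total - mean(total[ok])) / s)
}

#' Classify anthropometric status from z-scores
#'
#' Threshold flags per the standard WHO cutoffs: stunted if HAZ <= -2,
#' underweight if WAZ <= -2, wasted if WHZ <= -2. With `strict = TRUE` the
#' boundary value -2 is classified as not affected (HAZ < -2 variant).
#' Non-finite z-scores give missing flags; values with |z| > 6 are flagged
#' implausible.
#'
#' @param haz,waz,whz numeric vectors of height-for-age, weight-for-age and
#'   weight-for-height z-scores (any may be NULL).
#' @param strict logical; use strict inequality (< -2) instead of <= -2.
#' @return data.frame with the supplied z-scores, flags `stunted`,
#'   `underweight`, `wasted` (for the z-scores supplied) and a logical
#'   `implausible` column.
#' @examples
#' anthro_classify(haz = c(-2.5, -2, -1.9))$stunted  # 1 1 0
#' @export
anthro_classify <- function(haz = NULL, waz = NULL, whz = NULL,
                            strict = FALSE) {
  flag <- function(z) {
    z[!is.finite(z)] <- NA_real_
    if (strict) as.integer(z < -2) else as.integer(z <= -2)
  }
  inputs <- list(haz = haz, waz = waz, whz = whz)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  if (!length(inputs)) stop("supply at least one z-score vector", call. = FALSE)
  n <- unique(lengths(inputs))
  if (length(n) != 1L) stop("z-score vectors must have equal length", call. = FALSE)
  out <- as.data.frame(inputs)
  flags <- c(haz = "stunted", waz = "underweight", whz = "wasted")
  for (nm in names(inputs)) out[[flags[[nm]]]] <- flag(inputs[[nm]])
  zmat <- do.call(cbind, inputs)
  out$implausible <- apply(zmat, 1L, function(z) any(is.finite(z) & abs(z) > 6))
  out
}

#' Score all ECD outcomes for a sample of children
#'
#' Convenience wrapper combining [score_domain()], [unicef_composite()] and
#' [total_and_standardize()] for a 10-column item matrix (columns ordered
#' literacy 1-3, physical 1-2, learning 1-2, socio-emotional 1-3).
#'
#' @param items numeric matrix or data.frame with 10 binary item columns.
#' @return data.frame with columns `ontrack_literacy`, `ontrack_physical`,
#'   `ontrack_learning`, `ontrack_socioemotional`, `unicef_ontrack`,
#'   `total_score`, `ecdi_z`. Carries the standardization convention in
#'   attribute `"sd_type"`.
#' @export
score_ecd <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) != 10L) stop("expected 10 item columns", call. = FALSE)
  idx <- split(seq_len(10L), rep(names(ecd_domains), unlist(ecd_domains)))
  flags <- vapply(names(ecd_domains), function(d) {
    score_domain(items[, idx[[d]], drop = FALSE], d)
  }, integer(nrow(items)))
  if (is.null(dim(flags))) {
    flags <- matrix(flags, nrow = 1L, dimnames = list(NULL, names(ecd_domains)))
  }
  ts <- total_and_standardize(items)
  out <- data.frame(
    ontrack_literacy = flags[, "literacy"],
    ontrack_physical = flags[, "physical"],
    ontrack_learning = flags[, "learning"],
    ontrack_socioemotional = flags[, "socioemotional"],
    unicef_ontrack = unicef_composite(flags),
    total_score = ts$total_score,
    ecdi_z = ts$ecdi_z
  )
  attr(out, "sd_type") <- "sample (n-1)"
  out
}
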