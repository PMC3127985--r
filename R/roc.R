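# Discrimination: c-statistic (area under the ROC curve) and the DeLong
# placement-value method for its variance, confidence intervals, and paired
# comparisons of two models scored on the same persons.

check_binary_outcome <- function(y) {
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1 without missing values", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; the c-statistic is undefined",
         call. = FALSE)
  as.integer(y)
}

#' c-statistic (area under the ROC curve)
#'
#' Probability that a randomly chosen event receives a higher score than a
#' randomly chosen non-event, with ties counted half: (concordant pairs +
#' 0.5 x tied pairs) / (n_events x n_nonevents). Computed by midranks,
#' identical to brute-force pair enumeration.
#'
#' @param scores numeric model scores (higher = more risk).
#' @param y binary outcome vector.
#' @return the c-statistic in [0, 1].
#' @export
c_statistic <- function(scores, y) {
  y <- check_binary_outcome(y)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y); n0 <- sum(1 - y)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## DeLong placement values with midrank tie handling.
## V10: per-event fraction of non-events scored below it (ties half);
## V01: per-non-event fraction of events scored above it.
delong_placements <- function(scores, y) {
  n1 <- sum(y); n0 <- sum(1 - y)
  r_all <- rank(scores, ties.method = "average")
  r_case <- rank(scores[y == 1L], ties.method = "average")
  r_ctrl <- rank(scores[y == 0L], ties.method = "average")
  v10 <- (r_all[y == 1L] - r_case) / n0
  v01 <- 1 - (r_all[y == 0L] - r_ctrl) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

delong_variance <- function(pl, n1, n0) {
  s10 <- if (n1 > 1) stats::var(pl$v10) else 0
  s01 <- if (n0 > 1) stats::var(pl$v01) else 0
  s10 / n1 + s01 / n0
}

#' DeLong confidence interval for a single c-statistic
#'
#' c +/- z * sqrt(V) with V the DeLong placement-value variance; the
#' interval is truncated to [0, 1]. Perfect separation yields V = 0 and a
#' degenerate interval.
#'
#' @param scores numeric model scores.
#' @param y binary outcome vector.
#' @param level confidence level (default 0.95).
#' @return list with `c`, `ci_low`, `ci_high`, `var`.
#' @export
delong_ci <- function(scores, y, level = 0.95) {
  y <- check_binary_outcome(y)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y); n0 <- sum(1 - y)
  if (n1 < 2L || n0 < 2L)
    stop("DeLong variance needs at least 2 events and 2 non-events",
         call. = FALSE)
  pl <- delong_placements(scores, y)
  v <- delong_variance(pl, n1, n0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(max(v, 0))
  list(c = pl$auc, ci_low = max(0, pl$auc - half),
       ci_high = min(1, pl$auc + half), var = v)
}

#' DeLong paired test for two correlated c-statistics
#'
#' Tests `c_full - c_base` for two models scored on the same persons, using
#' the paired placement-value covariance. Identical score vectors give
#' delta = 0 and p = 1 by convention.
#'
#' @param scores_base,scores_full score vectors on the same persons.
#' @param y binary outcome vector.
#' @return list with `delta_c`, `z`, `p`, `var`.
#' @export
delong_paired_test <- function(scores_base, scores_full, y) {
  y <- check_binary_outcome(y)
  stopifnot(length(scores_base) == length(y),
            length(scores_full) == length(y))
  n1 <- sum(y); n0 <- sum(1 - y)
  if (n1 < 2L || n0 < 2L)
    stop("DeLong variance needs at least 2 events and 2 non-events",
         call. = FALSE)
  pa <- delong_placements(scores_base, y)
  pb <- delong_placements(scores_full, y)
  s10 <- stats::var(pa$v10) + stats::var(pb$v10) -
    2 * stats::cov(pa$v10, pb$v10)
  s01 <- stats::var(pa$v01) + stats::var(pb$v01) -
    2 * stats::cov(pa$v01, pb$v01)
  v <- s10 / n1 + s01 / n0
  delta <- pb$auc - pa$auc
  if (v <= .Machine$double.eps) {
    ## degenerate: no sampling variability in the difference
    z <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
  } else {
    z <- delta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(delta_c = delta, z = z, p = p, var = v)
}
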