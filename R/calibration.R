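# Calibration and paired-frequency tests: Brier score, Hosmer-Lemeshow
# goodness of fit, McNemar's test for overlapping cohorts.

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; 0 is perfect, 0.25 is attained by predicting 0.5 for everyone.
#' The reported SD is the sample standard deviation of the per-person
#' squared errors, the per-person quantity underlying the mean.
#'
#' @param probabilities predicted probabilities in [0, 1].
#' @param y binary outcome vector.
#' @return list with `score` and `sd`.
#' @export
brier <- function(probabilities, y) {
  if (length(probabilities) != length(y))
    stop("probabilities and outcomes differ in length", call. = FALSE)
  if (anyNA(probabilities) || any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  sq <- (probabilities - y)^2
  list(score = mean(sq), sd = if (length(sq) > 1) stats::sd(sq) else 0)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Persons are split into `groups` near-equal groups by predicted risk
#' (stable ordering; tied predictions are kept together in the lower
#' group); the statistic is sum (O - E)^2 / (E (1 - E/n_g)) over groups
#' with df = groups - 2.
#'
#' @param probabilities predicted probabilities.
#' @param y binary outcome vector.
#' @param groups number of risk groups (default 10).
#' @return list with `chi2`, `df`, `p`, and the per-group table `table`.
#' @export
hosmer_lemeshow <- function(probabilities, y, groups = 10L) {
  n <- length(y)
  stopifnot(length(probabilities) == n)
  if (n < 2L * groups)
    stop("need at least 2 observations per risk group", call. = FALSE)
  ord <- order(probabilities)             # stable for ties
  g <- ceiling(seq_len(n) * groups / n)
  ## keep tied predictions together: a tied run takes the lowest group it spans
  p_sorted <- probabilities[ord]
  g <- stats::ave(g, match(p_sorted, unique(p_sorted)), FUN = min)
  tab <- data.table::data.table(g = g, y = y[ord], p = p_sorted)[, .(
    n_g = .N, observed = sum(y), expected = sum(p)), by = g]
  if (any(tab$expected <= 0))
    stop("a risk group has zero expected events; use fewer groups",
         call. = FALSE)
  chi2 <- tab[, sum((observed - expected)^2 /
                      (expected * (1 - expected / n_g)))]
  df <- length(unique(g)) - 2L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       table = tab[])
}

#' McNemar's test for paired binary outcomes
#'
#' Compares the frequency of a binary outcome between two overlapping
#' cohorts on their shared members, using the discordant-pair counts b and
#' c: chi2 = (b - c)^2 / (b + c), uncorrected, with an exact binomial
#' p-value when b + c < 25. With no discordant pairs the test is undefined
#' and a no-discordance status is returned.
#'
#' @param outcomes_a,outcomes_b binary outcome vectors on the same persons.
#' @return list with `b`, `c`, `chi2`, `p`, `method`.
#' @export
mcnemar <- function(outcomes_a, outcomes_b) {
  stopifnot(length(outcomes_a) == length(outcomes_b))
  b <- sum(outcomes_a == 1 & outcomes_b == 0)
  cc <- sum(outcomes_a == 0 & outcomes_b == 1)
  if (b + cc == 0L)
    return(list(b = b, c = cc, chi2 = NA_real_, p = NA_real_,
                method = "no_discordance"))
  chi2 <- (b - cc)^2 / (b + cc)
  if (b + cc < 25L) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
    method <- "exact_binomial"
  } else {
    p <- stats::pchisq(chi2, 1L, lower.tail = FALSE)
    method <- "chi_square"
  }
  list(b = b, c = cc, chi2 = chi2, p = p, method = method)
}
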