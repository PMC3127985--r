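# Logistic risk models: base demographic model (age, age^2, sex, region,
# income quintile) plus one comorbidity term.

#' Model specification
#'
#' @param outcome one of `"death"`, `"hosp_ge1"`, `"hosp_ge2"`.
#' @param comorbidity_term `"none"` (the base model), one of the continuous
#'   measures (`"n_diagnoses"`, `"charlson"`, `"n_drugs"`, `"cds"`), or
#'   `"elixhauser_31"` which expands to 31 indicator columns.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(outcome = c("death", "hosp_ge1", "hosp_ge2"),
                       comorbidity_term = c("none", "n_diagnoses", "charlson",
                                            "elixhauser_31", "n_drugs", "cds")) {
  structure(list(outcome = match.arg(outcome),
                 comorbidity_term = match.arg(comorbidity_term)),
            class = "model_spec")
}

#' Build the logistic design matrix
#'
#' Columns: intercept, age (years), age squared, male indicator, region
#' indicators (reference: urban; missing region its own category), income
#' quintile indicators (reference: quintile 1; missing quintile its own
#' category), plus the comorbidity column(s). Zero-variance columns are
#' dropped with a warning (small cohorts can have empty categories).
#'
#' @param profiles comorbidity profiles from [build_profiles()].
#' @param demographics cohort member table (person_id, age_at_reference,
#'   sex, region, income_quintile), same persons as `profiles`.
#' @param spec a [model_spec()].
#' @return list with `X` (numeric matrix, persons in `demographics` order),
#'   `dropped` (names of pruned columns).
#' @export
build_design_matrix <- function(profiles, demographics, spec) {
  d <- data.table::as.data.table(demographics)
  p <- data.table::as.data.table(profiles)
  if (!all(d$person_id %in% p$person_id))
    stop("every member needs a comorbidity profile", call. = FALSE)
  p <- p[match(d$person_id, p$person_id)]
  age <- as.numeric(d$age_at_reference)
  X <- cbind(`(Intercept)` = 1, age = age, age_sq = age^2,
             male = as.numeric(d$sex == "M"),
             region_rural = as.numeric(d$region == "rural"),
             region_missing = as.numeric(d$region == "missing"))
  for (q in 2:5)
    X <- cbind(X, as.numeric(!is.na(d$income_quintile) & d$income_quintile == q))
  colnames(X)[(ncol(X) - 3):ncol(X)] <- paste0("quintile_", 2:5)
  X <- cbind(X, quintile_missing = as.numeric(is.na(d$income_quintile)))
  term <- spec$comorbidity_term
  if (term == "elixhauser_31") {
    cols <- sprintf("elix_%02d", 1:31)
    M <- as.matrix(p[, ..cols])
    colnames(M) <- elixhauser_conditions()
    X <- cbind(X, M)
  } else if (term != "none") {
    X <- cbind(X, as.numeric(p[[term]]))
    colnames(X)[ncol(X)] <- term
  }
  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  keep["(Intercept)"] <- TRUE
  dropped <- colnames(X)[!keep]
  if (length(dropped))
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  list(X = X[, keep, drop = FALSE], dropped = dropped)
}

#' Fit a logistic regression by maximum likelihood
#'
#' IRLS via `stats::glm.fit` with convergence tolerance 1e-8 and at most
#' 100 iterations. Collinear columns are pruned before fitting (with a
#' warning); perfect separation and non-convergence raise errors naming
#' the offending column / the diagnostics.
#'
#' @param X numeric design matrix including an intercept column.
#' @param y binary outcome vector.
#' @return list of class `fit_result`: `coefficients` (term, estimate, se),
#'   `fitted` (probabilities in member order), `converged`, `iterations`,
#'   `deviance`, `dropped`.
#' @export
fit_logistic <- function(X, y) {
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome is constant; refusing to fit", call. = FALSE)
  stopifnot(nrow(X) == length(y))
  ## rank check: drop aliased columns
  qrx <- qr(X)
  dropped <- character()
  if (qrx$rank < ncol(X)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(X)[-keep]
    warning("dropping collinear column(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    X <- X[, sort(keep), drop = FALSE]
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- fit$coefficients
  if (fit$deviance < 1e-6) {
    ## a binary outcome fit to zero deviance means perfect separation
    worst <- if (length(coefs) > 1) names(which.max(abs(coefs[-1])))
             else names(coefs)
    stop("perfect separation detected on column '", worst, "'",
         call. = FALSE)
  }
  if (sep_warn && any(abs(coefs[-1]) > 15))
    warning("quasi-separated column(s); extreme coefficient on '",
            names(which.max(abs(coefs[-1]))), "'", call. = FALSE)
  if (!fit$converged)
    stop(sprintf(paste0("logistic fit did not converge in %d iterations ",
                        "(deviance %.4f)"), fit$iter, fit$deviance),
         call. = FALSE)
  ## covariance (X'WX)^-1 via QR of sqrt(W) X: better conditioned than
  ## forming the information matrix (age^2 columns square its condition)
  w <- fit$fitted.values * (1 - fit$fitted.values)
  qa <- qr(X * sqrt(w))
  R <- qr.R(qa)
  cov <- chol2inv(R)
  piv <- qa$pivot %||% seq_len(ncol(X))
  se <- numeric(ncol(X))
  se[piv] <- sqrt(diag(cov))
  structure(list(
    coefficients = data.table::data.table(
      term = names(coefs), estimate = unname(coefs), se = se),
    fitted = fit$fitted.values,
    converged = fit$converged, iterations = fit$iter,
    deviance = fit$deviance, dropped = dropped), class = "fit_result")
}
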