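# Per-cohort model comparison: for each outcome fit the base demographic
# model and the five full models (base + one comorbidity measure) and
# quantify discrimination and calibration for each.

measure_terms <- function() {
  c("n_diagnoses", "charlson", "elixhauser_31", "n_drugs", "cds")
}

#' Evaluate all comorbidity measures on one cohort
#'
#' For each outcome (death, >=1 hospitalization, >=2 hospitalizations) fits
#' the base model and the five full models and reports, per model, the
#' c-statistic with its DeLong confidence interval, the Brier score with
#' its SD, the Hosmer-Lemeshow test, and, for full models, the change in c
#' against the base model (absolute, percent, and DeLong paired p-value).
#'
#' @param cohort a `cohort`.
#' @param profiles comorbidity profiles for the cohort members.
#' @param outcomes outcome indicators for the cohort members.
#' @param outcomes_used which outcomes to evaluate (default all three).
#' @param hl_groups Hosmer-Lemeshow group count (default 10).
#' @param ci_level confidence level for c-statistic intervals.
#' @return `data.table`, 6 rows per outcome (base + five measures):
#'   cohort, outcome, model, n, n_events, c, ci_low, ci_high, brier,
#'   brier_sd, delta_c, pct_change_c, p_delong, hl_chi2, hl_df, hl_p,
#'   unstable.
#' @export
evaluate_measures <- function(cohort, profiles, outcomes,
                              outcomes_used = c("death", "hosp_ge1", "hosp_ge2"),
                              hl_groups = 10L, ci_level = 0.95) {
  members <- cohort$members
  oc <- data.table::as.data.table(outcomes)
  oc <- oc[match(members$person_id, oc$person_id)]
  if (anyNA(oc$person_id))
    stop("every cohort member needs an outcome record", call. = FALSE)
  rows <- list()
  for (out_name in outcomes_used) {
    y <- oc[[out_name]]
    n_events <- sum(y)
    unstable <- n_events < 10L
    if (length(unique(y)) < 2L) {
      ## constant outcome: nothing estimable, report NA rows
      for (m in c("base", measure_terms()))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          cohort = cohort$label, outcome = out_name, model = m,
          n = length(y), n_events = n_events,
          c = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          brier = NA_real_, brier_sd = NA_real_, delta_c = NA_real_,
          pct_change_c = NA_real_, p_delong = NA_real_,
          hl_chi2 = NA_real_, hl_df = NA_integer_, hl_p = NA_real_,
          unstable = TRUE)
      next
    }
    safe_fit <- function(term) {
      X <- suppressWarnings(
        build_design_matrix(profiles, members, model_spec(out_name, term)))
      tryCatch(fit_logistic(X$X, y), error = function(e) {
        warning(sprintf("%s/%s/%s model not estimable: %s", cohort$label,
                        out_name, term, conditionMessage(e)), call. = FALSE)
        NULL
      })
    }
    na_row <- function(m) data.table::data.table(
      cohort = cohort$label, outcome = out_name, model = m,
      n = length(y), n_events = n_events,
      c = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      brier = NA_real_, brier_sd = NA_real_, delta_c = NA_real_,
      pct_change_c = NA_real_, p_delong = NA_real_,
      hl_chi2 = NA_real_, hl_df = NA_integer_, hl_p = NA_real_,
      unstable = TRUE)
    fit_b <- safe_fit("none")
    base_scores <- if (is.null(fit_b)) NULL else fit_b$fitted
    rows[[length(rows) + 1L]] <- if (is.null(fit_b)) na_row("base") else
      performance_row(cohort$label, out_name, "base", y, base_scores, NULL,
                      hl_groups, ci_level, unstable)
    for (term in measure_terms()) {
      fit_f <- safe_fit(term)
      rows[[length(rows) + 1L]] <- if (is.null(fit_f)) na_row(term) else
        performance_row(cohort$label, out_name, term, y, fit_f$fitted,
                        base_scores, hl_groups, ci_level, unstable)
    }
  }
  data.table::rbindlist(rows)
}

performance_row <- function(label, out_name, model_name, y, scores,
                            base_scores, hl_groups, ci_level, unstable) {
  ci <- delong_ci(scores, y, level = ci_level)
  br <- brier(scores, y)
  hl <- tryCatch(hosmer_lemeshow(scores, y, hl_groups),
                 error = function(e) list(chi2 = NA_real_, df = NA_integer_,
                                          p = NA_real_))
  if (is.null(base_scores)) {
    delta <- pct <- p_delong <- NA_real_
  } else {
    dt_test <- delong_paired_test(base_scores, scores, y)
    delta <- dt_test$delta_c
    pct <- 100 * delta / c_statistic(base_scores, y)
    p_delong <- dt_test$p
  }
  data.table::data.table(
    cohort = label, outcome = out_name, model = model_name,
    n = length(y), n_events = sum(y),
    c = ci$c, ci_low = ci$ci_low, ci_high = ci$ci_high,
    brier = br$score, brier_sd = br$sd,
    delta_c = delta, pct_change_c = pct, p_delong = p_delong,
    hl_chi2 = hl$chi2, hl_df = hl$df, hl_p = hl$p,
    unstable = unstable)
}

#' Compare outcome frequencies between two overlapping cohorts
#'
#' McNemar's test on the members shared by both cohorts, for each outcome.
#'
#' @param outcomes_a,outcomes_b outcome tables from [derive_outcomes()] for
#'   two cohorts with overlapping membership.
#' @return `data.table`: outcome, n_shared, b, c, chi2, p, method.
#' @export
compare_cohort_outcomes <- function(outcomes_a, outcomes_b) {
  shared <- intersect(outcomes_a$person_id, outcomes_b$person_id)
  a <- outcomes_a[match(shared, person_id)]
  b <- outcomes_b[match(shared, person_id)]
  data.table::rbindlist(lapply(c("death", "hosp_ge1", "hosp_ge2"), function(oc) {
    m <- mcnemar(a[[oc]], b[[oc]])
    data.table::data.table(outcome = oc, n_shared = length(shared),
                           b = m$b, c = m$c, chi2 = m$chi2, p = m$p,
                           method = m$method)
  }))
}
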