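# Outcome derivation over the outcome fiscal year: death, >=1
# hospitalization, >=2 hospitalizations.

#' Derive the death indicator
#'
#' Death = 1 iff the registry/vital-statistics death date falls inside the
#' outcome window. A death date before the cohort's reference date is an
#' integrity error: such a person should never have entered the cohort.
#'
#' @param bundle a `claims_bundle`.
#' @param cohort a `cohort`.
#' @param window two dates (default: the bundle's outcome year).
#' @return `data.table` with person_id, death.
#' @export
derive_death <- function(bundle, cohort, window = bundle$outcome_year) {
  window <- as_date(window)
  reg <- bundle$registry[person_id %in% cohort$members$person_id,
                         .(person_id, death_date)]
  bad <- reg[!is.na(death_date) & death_date < cohort$spec$as_of_date]
  if (nrow(bad))
    stop("integrity error: ", nrow(bad), " cohort member(s) died before the ",
         "reference date and should have been excluded", call. = FALSE)
  reg[, .(person_id,
          death = as.integer(!is.na(death_date) &
                             death_date >= window[1] & death_date <= window[2]))]
}

#' Derive hospitalization outcomes
#'
#' Counts hospital abstracts with an admission date inside the window whose
#' most responsible diagnosis is not pregnancy/childbirth/abortion-related
#' (secondary pregnancy codes do not exclude a stay). Transfers and
#' readmissions count as separate records; no episode linkage is attempted.
#'
#' @param bundle a `claims_bundle`.
#' @param cohort a `cohort`.
#' @param window two dates (default: the bundle's outcome year).
#' @param exclusions pregnancy exclusion code set.
#' @return `data.table` with person_id, n_hospitalizations, hosp_ge1,
#'   hosp_ge2.
#' @export
derive_hospitalizations <- function(bundle, cohort,
                                    window = bundle$outcome_year,
                                    exclusions = load_pregnancy_exclusions()) {
  window <- as_date(window)
  ids <- cohort$members$person_id
  h <- bundle$hospital[person_id %in% ids &
                       admission_date >= window[1] &
                       admission_date <= window[2]]
  out <- data.table::data.table(person_id = ids, key = "person_id")
  out[, n_hospitalizations := 0L]
  if (nrow(h)) {
    ## one row per admission, judged on its most responsible diagnosis
    adm <- h[dx_type == "most_responsible",
             .(person_id, admission_date, code = normalize_code(code), system)]
    ## admissions recorded without an explicit most-responsible row still count
    all_adm <- unique(h[, .(person_id, admission_date)])
    adm_mr <- unique(adm[, .(person_id, admission_date)])
    no_mr <- all_adm[!adm_mr, on = c("person_id", "admission_date")]
    keep <- adm[!is_pregnancy_code(system, code)]
    counts <- data.table::rbindlist(list(
      unique(keep[, .(person_id, admission_date)]), no_mr))
    cnt <- counts[, .N, by = person_id]
    out[cnt, n_hospitalizations := i.N, on = "person_id"]
  }
  out[, `:=`(hosp_ge1 = as.integer(n_hospitalizations >= 1L),
             hosp_ge2 = as.integer(n_hospitalizations >= 2L))]
  out[]
}

#' Derive all outcome indicators for a cohort
#'
#' @inheritParams derive_hospitalizations
#' @return `data.table` with person_id, death, hosp_ge1, hosp_ge2,
#'   n_hospitalizations.
#' @export
derive_outcomes <- function(bundle, cohort, window = bundle$outcome_year) {
  d <- derive_death(bundle, cohort, window)
  h <- derive_hospitalizations(bundle, cohort, window)
  out <- merge(d, h, by = "person_id")
  data.table::setcolorder(out, c("person_id", "death", "hosp_ge1", "hosp_ge2",
                                 "n_hospitalizations"))
  out[]
}

#' Write outcomes as CSV
#'
#' @param outcomes output of [derive_outcomes()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_outcomes <- function(outcomes, file) {
  data.table::fwrite(outcomes, file)
  invisible(file)
}
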