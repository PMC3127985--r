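# Cohort construction from a claims bundle.
#
# Three cohorts: the general adult population, a diabetes cohort (one
# hospital diagnosis or two physician claims within two years), and an
# osteoporosis cohort (one diagnosis or one osteoprotective dispensation,
# Paget's disease excluded). Eligibility in all three requires uninterrupted
# health coverage over the comorbidity and outcome years and being alive at
# the reference date; "uninterrupted" is satisfied up to the death date for
# persons dying inside the coverage period, since death is itself a study
# outcome.

#' Cohort specification
#'
#' @param label one of `"general"`, `"diabetes"`, `"osteoporosis"`.
#' @param min_age age floor in completed years at `as_of_date`; defaults to
#'   20 for general/diabetes and 50 for osteoporosis.
#' @param case_window two dates bounding case finding for the disease
#'   cohorts (default: the six study fiscal years).
#' @param coverage_period two dates over which uninterrupted coverage is
#'   required (default: comorbidity + outcome years).
#' @param as_of_date the single reference date at which age and vital status
#'   are assessed (default 2002-04-01, the start of the outcome year).
#' @return a validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(label = c("general", "diabetes", "osteoporosis"),
                        min_age = NULL,
                        case_window = fy_study_window(),
                        coverage_period = c(fy_comorbidity()[1], fy_outcome()[2]),
                        as_of_date = fy_outcome()[1]) {
  label <- match.arg(label)
  min_age <- min_age %||% if (label == "osteoporosis") 50L else 20L
  case_window <- check_interval(case_window, "case_window")
  coverage_period <- check_interval(coverage_period, "coverage_period")
  if (case_window[2] > coverage_period[2])
    stop_config("case_window", "must end no later than the coverage period")
  structure(list(label = label, min_age = as.integer(min_age),
                 case_window = case_window, coverage_period = coverage_period,
                 as_of_date = as_date(as_of_date)),
            class = "cohort_spec")
}

#' Uninterrupted-coverage predicate
#'
#' TRUE when the union of a person's coverage intervals contains `period`
#' with no gap, or contains it up to the person's death date when death
#' falls inside the period (decedents stay eligible because death is a
#' study outcome).
#'
#' @param intervals data.frame/data.table with columns `coverage_start`,
#'   `coverage_end` (inclusive dates), non-overlapping.
#' @param period two dates (start, end).
#' @param death_date optional death date.
#' @return logical scalar.
#' @export
has_continuous_coverage <- function(intervals, period, death_date = NULL) {
  period <- as_date(period)
  p0 <- period[1]; p1 <- period[2]
  if (!is.null(death_date) && length(death_date) && !is.na(death_date)) {
    dd <- as_date(death_date)
    if (dd >= p0 && dd <= p1) p1 <- dd
  }
  iv <- data.table::as.data.table(intervals)
  if (!nrow(iv)) return(FALSE)
  data.table::setorder(iv, coverage_start)
  s <- as_date(iv$coverage_start); e <- as_date(iv$coverage_end)
  keep <- e >= p0 & s <= p1
  if (!any(keep)) return(FALSE)
  s <- s[keep]; e <- e[keep]
  if (s[1] > p0) return(FALSE)
  reach <- e[1]
  if (length(s) > 1) for (i in 2:length(s)) {
    if (s[i] > reach + 1L) break       # gap of at least one uncovered day
    reach <- max(reach, e[i])
  }
  reach >= p1
}

## Vectorized form: person_ids from `registry` satisfying the coverage rule.
covered_person_ids <- function(registry, coverage, period) {
  period <- as_date(period)
  p0 <- period[1]; p1 <- period[2]
  dd <- registry[, .(person_id, death_date)]
  cov <- merge(coverage[person_id %in% dd$person_id], dd,
               by = "person_id", all.x = TRUE)
  ## effective period end: death date when death falls inside the period
  cov[, pe := p1]
  cov[!is.na(death_date) & death_date >= p0 & death_date <= p1,
      pe := death_date]
  rel <- cov[coverage_end >= p0 & coverage_start <= pe]
  if (!nrow(rel)) return(character())
  data.table::setorder(rel, person_id, coverage_start)
  rel[, gap := coverage_start >
        data.table::shift(coverage_end, fill = coverage_start[1] - 1L) + 1L,
      by = person_id]
  qual <- rel[, .(ok = coverage_start[1] <= p0 & coverage_end[.N] >= pe[1] &
                    !any(gap)), by = person_id]
  qual[ok == TRUE, person_id]
}

## Demographics + filters shared by all cohort builders.
finalize_cohort <- function(bundle, spec, candidates, index_dates = NULL) {
  reg <- bundle$registry
  members <- reg[person_id %in% candidates]
  if (!nrow(members))
    warning("cohort '", spec$label, "' is empty", call. = FALSE)
  members[, age_at_reference := age_at(birth_date, spec$as_of_date)]
  alive <- is.na(members$death_date) | members$death_date >= spec$as_of_date
  members <- members[alive & age_at_reference >= spec$min_age]
  covered <- covered_person_ids(members, bundle$coverage, spec$coverage_period)
  members <- members[person_id %in% covered]
  out <- members[, .(person_id, age_at_reference, sex, region, income_quintile)]
  if (!is.null(index_dates)) {
    out <- merge(out, index_dates, by = "person_id", all.x = TRUE)
  } else {
    out[, index_date := as.Date(NA)]
  }
  data.table::setorder(out, person_id)
  data.table::setcolorder(out, c("person_id", "index_date", "age_at_reference",
                                 "sex", "region", "income_quintile"))
  structure(list(label = spec$label, spec = spec, members = out),
            class = "cohort")
}

#' Build the general population cohort
#'
#' All registered persons aged `min_age` (default 20) and over at the
#' reference date, alive at that date, with uninterrupted coverage over the
#' coverage period. No index date.
#'
#' @param bundle a `claims_bundle`.
#' @param spec a [cohort_spec()] with label `"general"`.
#' @return a `cohort`: list with `label`, `spec`, and `members` (person_id,
#'   index_date, age_at_reference, sex, region, income_quintile).
#' @export
build_general_cohort <- function(bundle, spec = cohort_spec("general")) {
  stopifnot(spec$label == "general")
  finalize_cohort(bundle, spec, bundle$registry$person_id)
}

## Hospital + physician diagnosis events matching a cohort-map condition
## inside a window: returns person_id, date, source.
case_matches <- function(bundle, cond_name, window) {
  map <- load_condition_map("cohort")
  map <- map[condition == cond_name]
  hosp <- bundle$hospital[admission_date >= window[1] & admission_date <= window[2]]
  phys <- bundle$physician[service_date >= window[1] & service_date <= window[2]]
  out <- list()
  if (nrow(hosp)) {
    hosp <- data.table::copy(hosp)[, code := normalize_code(code)]
    m <- match_codes(hosp[, .(system, code)], map)
    if (nrow(m)) {
      hit <- hosp[m[, .(system, code)], on = c("system", "code"), nomatch = NULL]
      out[["hospital"]] <- hit[, .(person_id, date = admission_date,
                                   source = "hospital")]
    }
  }
  if (nrow(phys)) {
    ph <- data.table::copy(phys)[, `:=`(system = "ICD9",
                                        code = normalize_code(diagnosis))]
    m <- match_codes(ph[, .(system, code)], map)
    if (nrow(m)) {
      hit <- ph[m[, .(system, code)], on = c("system", "code"), nomatch = NULL]
      out[["physician"]] <- hit[, .(person_id, date = service_date,
                                    source = "physician")]
    }
  }
  if (!length(out))
    return(data.table::data.table(person_id = character(),
                                  date = as.Date(character()),
                                  source = character()))
  data.table::rbindlist(out)
}

#' Build the diabetes cohort
#'
#' Case definition: at least one hospital diagnosis of diabetes (ICD-9 250,
#' ICD-10 E10-E14) in the case window, or at least two physician claims with
#' such codes whose service dates lie within 730 days of each other. The
#' index date is the earliest qualifying diagnosis date. Age, vital-status
#' and coverage filters are then applied as for the general cohort.
#'
#' @param bundle a `claims_bundle`.
#' @param spec a [cohort_spec()] with label `"diabetes"`.
#' @return a `cohort`.
#' @export
build_diabetes_cohort <- function(bundle, spec = cohort_spec("diabetes")) {
  stopifnot(spec$label == "diabetes")
  ev <- case_matches(bundle, "diabetes_case", spec$case_window)
  hosp_idx <- ev[source == "hospital", .(index_date = min(date)), by = person_id]
  phys_idx <- ev[source == "physician"][order(person_id, date)][, {
    ## sliding two-year window: any pair of claims <= 730 days apart
    ## qualifies; index is the first claim of the earliest such pair
    if (.N >= 2L) {
      gaps <- as.integer(diff(date))
      k <- which(gaps <= 730L)
      if (length(k)) .(index_date = date[k[1]]) else .(index_date = as.Date(NA))
    } else .(index_date = as.Date(NA))
  }, by = person_id][!is.na(index_date)]
  idx <- data.table::rbindlist(list(hosp_idx, phys_idx))
  if (nrow(idx)) idx <- idx[, .(index_date = min(index_date)), by = person_id]
  finalize_cohort(bundle, spec, idx$person_id, idx)
}

#' Build the osteoporosis cohort
#'
#' Case definition: at least one diagnosis of osteoporosis (ICD-9 733,
#' ICD-10 M80/M81) in hospital or physician data, or at least one
#' dispensation of an osteoprotective medication (bisphosphonates, salmon
#' calcitonin, raloxifene, teriparatide), inside the case window. Persons
#' with any Paget's disease diagnosis (ICD-9 731.0, ICD-10 M88.0/.8/.9) in
#' the window are excluded. The index date is the earliest qualifying
#' diagnosis or dispensation.
#'
#' @param bundle a `claims_bundle`.
#' @param spec a [cohort_spec()] with label `"osteoporosis"` (age floor 50).
#' @return a `cohort`.
#' @export
build_osteoporosis_cohort <- function(bundle, spec = cohort_spec("osteoporosis")) {
  stopifnot(spec$label == "osteoporosis")
  dx <- case_matches(bundle, "osteoporosis", spec$case_window)
  drugs <- bundle$drugs[dispense_date >= spec$case_window[1] &
                        dispense_date <= spec$case_window[2]]
  med <- load_osteoporosis_drugs()
  ## ingredient label when present, AHFS-class fallback otherwise
  qd <- drugs[(!is.na(ingredient) & tolower(ingredient) %in% med$ingredient) |
              (is.na(ingredient) & ahfs_class %in% med$ahfs_class)]
  ev <- data.table::rbindlist(list(
    dx[, .(person_id, date)],
    qd[, .(person_id, date = dispense_date)]))
  idx <- if (nrow(ev)) ev[, .(index_date = min(date)), by = person_id]
         else data.table::data.table(person_id = character(),
                                     index_date = as.Date(character()))
  paget <- case_matches(bundle, "pagets_disease", spec$case_window)
  idx <- idx[!person_id %in% unique(paget$person_id)]
  finalize_cohort(bundle, spec, idx$person_id, idx)
}

#' Build a cohort by label
#'
#' @param bundle a `claims_bundle`.
#' @param spec a [cohort_spec()].
#' @return a `cohort`.
#' @export
build_cohort <- function(bundle, spec) {
  switch(spec$label,
         general = build_general_cohort(bundle, spec),
         diabetes = build_diabetes_cohort(bundle, spec),
         osteoporosis = build_osteoporosis_cohort(bundle, spec))
}

#' Restrict a cohort to an age floor
#'
#' @param cohort a `cohort`.
#' @param min_age inclusive age floor in completed years (default 65).
#' @return a `cohort` containing the members with
#'   `age_at_reference >= min_age`; all other fields unchanged.
#' @export
restrict_age <- function(cohort, min_age = 65L) {
  stopifnot(inherits(cohort, "cohort"))
  out <- cohort
  out$members <- cohort$members[age_at_reference >= min_age]
  out$spec$min_age <- as.integer(min_age)
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s': %d members, age >= %d at %s>\n",
              x$label, nrow(x$members), x$spec$min_age,
              format(x$spec$as_of_date)))
  invisible(x)
}

#' Write cohort membership as CSV
#'
#' @param cohort a `cohort`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_cohort <- function(cohort, file) {
  out <- data.table::copy(cohort$members)
  out[, label := cohort$label]
  data.table::setcolorder(out, c("person_id", "label", "index_date",
                                 "age_at_reference", "sex", "region",
                                 "income_quintile"))
  data.table::fwrite(out, file, dateTimeAs = "ISO")
  invisible(file)
}
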