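# Synthetic linked administrative claims generator.
#
# Emulates the five linked tables of a provincial claims system (population
# registry with coverage intervals, hospital discharge abstracts with typed
# ICD-9/ICD-10 diagnoses, 3-digit ICD-9 physician claims, AHFS-classified
# drug dispensations, vital statistics) with known latent condition flags and
# known outcome-generating models, so that cohort construction, comorbidity
# scoring and model evaluation can be validated end to end. The `truth`
# table is for recovery tests only and is never read by analysis modules.

#' Default latent-condition prevalences
#'
#' Annual prevalences of the latent chronic conditions used by the
#' generator: the 31 Elixhauser categories at general-adult-population
#' rates, plus the two cohort-defining conditions (osteoporosis among
#' adults, Paget's disease). Copy and modify to change study conditions.
#'
#' @return named numeric vector of prevalences in [0, 1].
#' @export
default_condition_prevalences <- function() {
  c(hypertension_uncomplicated = 0.167, chronic_pulmonary_disease = 0.084,
    depression = 0.056, hypothyroidism = 0.034, solid_tumor = 0.025,
    congestive_heart_failure = 0.020, psychoses = 0.013,
    rheumatoid_arthritis = 0.012, diabetes_complicated = 0.010,
    valvular_disease = 0.010, other_neurological_disorders = 0.010,
    cardiac_arrhythmias = 0.008, fluid_electrolyte_disorders = 0.008,
    coagulopathy = 0.008, metastatic_cancer = 0.008, renal_failure = 0.006,
    drug_abuse = 0.005, peripheral_vascular_disease = 0.004,
    deficiency_anemia = 0.004, hypertension_complicated = 0.003,
    pulmonary_circulation_disorders = 0.003, liver_disease = 0.003,
    alcohol_abuse = 0.003, diabetes_uncomplicated = 0.025, obesity = 0.002,
    paralysis = 0.002, peptic_ulcer_disease = 0.001, lymphoma = 0.001,
    weight_loss = 0.001, blood_loss_anemia = 0.001, aids_hiv = 0.0005,
    osteoporosis = 0.040, pagets_disease = 0.001)
}

#' Default outcome-generating coefficients
#'
#' `default_death_coefficients()` gives heterogeneous per-condition
#' log-odds effects on one-year death: strong effects for metastatic
#' cancer, heart failure, organ failure and wasting, weak or null effects
#' for e.g. uncomplicated hypertension. This spread in effect size is what
#' an indicator-per-condition model can exploit and a single summary count
#' cannot. `default_hospitalization_coefficients()` gives the log-linear
#' Poisson rate for outcome-year admissions, driven by total latent
#' diagnosis burden. Intercepts are calibrated so that the generated
#' general adult population shows roughly 1.3% one-year death, 17%
#' with at least one admission and 5% with two or more.
#'
#' @return named numeric coefficient vector (logit scale for death,
#'   log-rate scale for hospitalization).
#' @export
default_death_coefficients <- function() {
  c("(Intercept)" = -5.40, age_dec = 0.90, male = 0.35,
    metastatic_cancer = 2.50, weight_loss = 1.40, lymphoma = 1.30,
    congestive_heart_failure = 1.30, renal_failure = 1.20,
    liver_disease = 1.20, aids_hiv = 1.50, solid_tumor = 1.00,
    fluid_electrolyte_disorders = 0.90, alcohol_abuse = 0.80,
    coagulopathy = 0.70, other_neurological_disorders = 0.70,
    paralysis = 0.70, pulmonary_circulation_disorders = 0.70,
    cardiac_arrhythmias = 0.60, chronic_pulmonary_disease = 0.60,
    peripheral_vascular_disease = 0.60, diabetes_complicated = 0.60,
    drug_abuse = 0.60, valvular_disease = 0.40, psychoses = 0.40,
    deficiency_anemia = 0.40, blood_loss_anemia = 0.40,
    hypertension_complicated = 0.40, diabetes_uncomplicated = 0.30,
    peptic_ulcer_disease = 0.30, rheumatoid_arthritis = 0.30,
    obesity = 0.20, osteoporosis = 0.20, depression = 0.10,
    hypertension_uncomplicated = 0.10)
}

#' @rdname default_death_coefficients
#' @export
default_hospitalization_coefficients <- function() {
  c("(Intercept)" = -2.63, age_dec = 0.15, male = -0.05, burden = 0.26)
}

#' Build and validate a synthetic-claims generator configuration
#'
#' Defaults emulate a general adult provincial population observed over the
#' 1996/97-2001/02 fiscal study window, with comorbidity assessed in fiscal
#' 2001/02 and outcomes in 2002/03. Latent condition prevalences default to
#' general-population rates for the 31 Elixhauser categories; the death model
#' is logistic with heterogeneous condition effects, and the hospitalization
#' model is Poisson on a log-linear predictor in total diagnosis burden, so
#' each generated dataset carries a known ground truth.
#'
#' @param n_persons number of persons in the registry.
#' @param seed integer seed; the bundle is a pure function of (config, seed).
#' @param study_window two dates bounding multi-year history generation.
#' @param comorbidity_year two dates bounding the comorbidity assessment year.
#' @param outcome_year two dates bounding the outcome year.
#' @param age_range minimum and maximum age (years) at the start of the
#'   outcome year.
#' @param female_fraction,urban_fraction demographic proportions.
#' @param condition_prevalences named vector of annual prevalences in [0,1];
#'   names must exist in the bundled condition maps.
#' @param drug_class_rate mean number of distinct background (non
#'   condition-linked) AHFS drug classes dispensed per person-year.
#' @param death_coefficients named logit-scale coefficients; names are
#'   `(Intercept)`, `age_dec` ((age-60)/10), `male`, `burden`, or condition
#'   names.
#' @param hospitalization_coefficients named log-rate coefficients; same
#'   naming rules.
#' @param coverage_gap_fraction proportion of persons given a coverage gap
#'   inside the comorbidity/outcome period.
#' @param region_missing,quintile_missing proportions with unassignable
#'   region / income quintile.
#' @param physician_channel_prob probability that a condition's assessment-
#'   year code is emitted through physician claims when the condition is
#'   detectable from a 3-digit ICD-9 code (otherwise hospital).
#' @param cohort_detect_prob probability that a latent cohort condition
#'   (diabetes, osteoporosis) emits case-qualifying codes in the study window.
#' @param treat_prob probability that a latent condition linked to a drug
#'   class emits a dispensation in the assessment year.
#' @param noise_dx_mean,noise_dx_size negative-binomial mean and size for the
#'   count of acute (non-chronic) distinct diagnoses per person-year.
#' @param pregnancy_event_rate probability that a woman of childbearing age
#'   has a pregnancy/delivery-coded contact in a given year.
#' @param complication_dx_prob probability that a hospital abstract carries an
#'   extra post-admission complication diagnosis.
#' @param era_realism if TRUE, hospital abstracts are coded ICD-9 before
#'   2002-04-01 and ICD-10 after; if FALSE (default) the system is mixed
#'   regardless of date so both dialects are exercised everywhere.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_persons = 1000L,
                             seed = 1L,
                             study_window = fy_study_window(),
                             comorbidity_year = fy_comorbidity(),
                             outcome_year = fy_outcome(),
                             age_range = c(20, 105),
                             female_fraction = 0.513,
                             urban_fraction = 0.582,
                             condition_prevalences = default_condition_prevalences(),
                             drug_class_rate = 1.3,
                             death_coefficients = default_death_coefficients(),
                             hospitalization_coefficients = default_hospitalization_coefficients(),
                             coverage_gap_fraction = 0.05,
                             region_missing = 0.002,
                             quintile_missing = 0.012,
                             physician_channel_prob = 0.7,
                             cohort_detect_prob = 0.95,
                             treat_prob = 0.7,
                             noise_dx_mean = 3.4,
                             noise_dx_size = 0.9,
                             pregnancy_event_rate = 0.04,
                             complication_dx_prob = 0.10,
                             era_realism = FALSE) {
  if (!is_scalar_number(n_persons) || n_persons < 1 || n_persons != round(n_persons))
    stop_config("n_persons", "must be a positive integer")
  if (!is_scalar_number(seed) || seed != round(seed))
    stop_config("seed", "must be an integer")
  study_window <- check_interval(study_window, "study_window")
  comorbidity_year <- check_interval(comorbidity_year, "comorbidity_year")
  outcome_year <- check_interval(outcome_year, "outcome_year")
  if (length(age_range) != 2L || age_range[1] > age_range[2] || age_range[1] < 0)
    stop_config("age_range", "must be ordered non-negative (min, max) years")
  for (f in c("female_fraction", "urban_fraction", "coverage_gap_fraction",
              "region_missing", "quintile_missing", "physician_channel_prob",
              "cohort_detect_prob", "treat_prob", "pregnancy_event_rate",
              "complication_dx_prob"))
    check_proportion(get(f), f)
  if (!is_scalar_number(drug_class_rate) || drug_class_rate < 0)
    stop_config("drug_class_rate", "must be a non-negative rate")
  if (!is_scalar_number(noise_dx_mean) || noise_dx_mean < 0)
    stop_config("noise_dx_mean", "must be a non-negative mean")
  if (!is_scalar_number(noise_dx_size) || noise_dx_size <= 0)
    stop_config("noise_dx_size", "must be positive")
  if (is.null(names(condition_prevalences)) ||
      any(!nzchar(names(condition_prevalences))))
    stop_config("condition_prevalences", "must be a named vector")
  if (any(condition_prevalences < 0 | condition_prevalences > 1))
    stop_config("condition_prevalences", "prevalences must lie in [0, 1]")
  known <- known_condition_names()
  bad <- setdiff(names(condition_prevalences), known)
  if (length(bad))
    stop_config("condition_prevalences",
                paste("unknown condition(s):", paste(bad, collapse = ", ")))
  for (nm in c("death_coefficients", "hospitalization_coefficients")) {
    cf <- get(nm)
    if (is.null(names(cf)) || any(!nzchar(names(cf))))
      stop_config(nm, "must be a named numeric vector")
    allowed <- c("(Intercept)", "age_dec", "male", "burden", known)
    bad <- setdiff(names(cf), allowed)
    if (length(bad))
      stop_config(nm, paste("unknown covariate(s):", paste(bad, collapse = ", ")))
  }
  structure(list(
    n_persons = as.integer(n_persons), seed = as.integer(seed),
    study_window = study_window, comorbidity_year = comorbidity_year,
    outcome_year = outcome_year, age_range = age_range,
    female_fraction = female_fraction, urban_fraction = urban_fraction,
    condition_prevalences = condition_prevalences,
    drug_class_rate = drug_class_rate,
    death_coefficients = death_coefficients,
    hospitalization_coefficients = hospitalization_coefficients,
    coverage_gap_fraction = coverage_gap_fraction,
    region_missing = region_missing, quintile_missing = quintile_missing,
    physician_channel_prob = physician_channel_prob,
    cohort_detect_prob = cohort_detect_prob, treat_prob = treat_prob,
    noise_dx_mean = noise_dx_mean, noise_dx_size = noise_dx_size,
    pregnancy_event_rate = pregnancy_event_rate,
    complication_dx_prob = complication_dx_prob,
    era_realism = isTRUE(era_realism)), class = "generator_config")
}

## Names the generator accepts as latent conditions: the union of the
## bundled diagnosis maps.
known_condition_names <- function() {
  unique(c(unique(load_condition_map("elixhauser")$condition),
           unique(load_condition_map("charlson")$condition),
           unique(load_condition_map("cohort")$condition)))
}

## ---------------------------------------------------------------------------
## Emission codes: one representative full code per condition and system,
## derived from the first bundled pattern, plus (when one exists) a 3-digit
## ICD-9 code usable on physician claims. Conditions whose shortest ICD-9
## pattern exceeds 3 characters are only detectable from hospital data.
pattern_example <- function(pattern_type, pattern) {
  if (pattern_type == "range") strsplit(pattern, "-", fixed = TRUE)[[1]][1]
  else pattern
}

emission_codes <- function() {
  cached_table("emission_codes", build_emission_codes())
}

build_emission_codes <- function() {
  maps <- data.table::rbindlist(list(
    load_condition_map("elixhauser")[, .(condition, system, pattern_type, pattern)],
    load_condition_map("charlson")[, .(condition, system, pattern_type, pattern)],
    load_condition_map("cohort")[, .(condition, system, pattern_type, pattern)]),
    use.names = TRUE)
  maps <- unique(maps)
  out <- maps[, {
    ex <- vapply(seq_len(.N), function(i) pattern_example(pattern_type[i], pattern[i]), "")
    icd9  <- ex[system == "ICD9"]
    icd10 <- ex[system == "ICD10"]
    short9 <- icd9[nchar(icd9) <= 3L]
    .(icd9_code  = if (length(icd9))  icd9[1]  else NA_character_,
      icd10_code = if (length(icd10)) icd10[1] else NA_character_,
      icd9_3digit = if (length(short9)) short9[1] else NA_character_)
  }, by = condition]
  out
}

## Acute "noise" diagnosis code pools (injury rubrics): verified at load time
## to be disjoint from every bundled condition map and from the pregnancy
## exclusion set, so noise events never move a condition flag.
noise_code_pools <- function() {
  cached_table("noise_code_pools", build_noise_code_pools())
}

build_noise_code_pools <- function() {
  icd9  <- sprintf("8%02d", 0:99)          # 800-899
  icd10 <- sprintf("S%02d", 0:99)          # S00-S99
  pool <- data.table::data.table(
    system = rep(c("ICD9", "ICD10"), c(length(icd9), length(icd10))),
    code = c(icd9, icd10))
  maps <- list(load_condition_map("elixhauser"), load_condition_map("charlson"),
               load_condition_map("cohort"), load_pregnancy_exclusions())
  for (m in maps) {
    hit <- match_codes(pool, m)
    if (nrow(hit)) pool <- pool[!code %in% hit$code]
  }
  pool
}

## Background AHFS drug classes not used by the CDS table (checked at load).
background_drug_classes <- function() {
  cached_table("background_drug_classes", build_background_drug_classes())
}

build_background_drug_classes <- function() {
  pool <- c("08:12", "08:18", "28:08", "28:16", "28:24", "36:26", "40:12",
            "48:16", "52:04", "56:12", "56:22", "64:00", "80:08", "84:04",
            "84:06", "88:08", "88:16", "92:02", "92:12")
  cds <- load_cds_map()$classes$ahfs_class
  setdiff(pool, cds)
}

## Latent condition -> CDS condition whose drug classes it draws from.
cds_condition_links <- function() {
  c(hypertension_uncomplicated = "hypertension",
    hypertension_complicated = "hypertension",
    chronic_pulmonary_disease = "respiratory_illness",
    congestive_heart_failure = "heart_disease",
    cardiac_arrhythmias = "heart_disease",
    valvular_disease = "heart_disease",
    diabetes_uncomplicated = "diabetes",
    diabetes_complicated = "diabetes",
    hypothyroidism = "thyroid_disorder",
    solid_tumor = "cancer", metastatic_cancer = "cancer", lymphoma = "cancer",
    rheumatoid_arthritis = "rheumatoid_arthritis",
    peptic_ulcer_disease = "ulcers",
    other_neurological_disorders = "epilepsy",
    peripheral_vascular_disease = "high_cholesterol")
}

## ---------------------------------------------------------------------------

#' Generate the population registry
#'
#' Draws demographics (age from a shifted gamma, sex, urban/rural region,
#' income quintile with a missing category) and provincial-coverage
#' intervals; a configured fraction of persons receives a coverage gap
#' inside the comorbidity/outcome period. Death dates are assigned later by
#' [generate_outcome_year()].
#'
#' @param config a [generator_config()].
#' @return list with `persons` (one row per person) and `coverage`
#'   (person_id, coverage_start, coverage_end; non-overlapping, ordered).
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed + 101L, {
    n <- config$n_persons
    as_of <- config$outcome_year[1]
    age <- config$age_range[1] + stats::rgamma(n, shape = 2.4, scale = 11.6)
    age <- pmin(age, config$age_range[2])
    birth_date <- as_of - as.integer(round(age * 365.25 + runif(n, 0, 364)))
    sex <- ifelse(runif(n) < config$female_fraction, "F", "M")
    region <- ifelse(runif(n) < config$region_missing, "missing",
                     ifelse(runif(n) < config$urban_fraction, "urban", "rural"))
    quintile <- ifelse(runif(n) < config$quintile_missing, NA_integer_,
                       sample.int(5L, n, replace = TRUE))
    persons <- data.table::data.table(
      person_id = sprintf("P%07d", seq_len(n)),
      birth_date = birth_date, sex = sex, region = region,
      income_quintile = as.integer(quintile),
      death_date = as.Date(NA))
    cov_start <- config$study_window[1] - 365L
    cov_end <- config$outcome_year[2]
    gap <- runif(n) < config$coverage_gap_fraction
    gap_at <- config$comorbidity_year[1] +
      as.integer(floor(runif(n) * as.integer(config$outcome_year[2] -
                                             config$comorbidity_year[1] - 70L)))
    gap_len <- as.integer(1L + floor(runif(n) * 60))
    coverage <- data.table::rbindlist(list(
      data.table::data.table(person_id = persons$person_id[!gap],
                             coverage_start = cov_start, coverage_end = cov_end),
      data.table::data.table(person_id = persons$person_id[gap],
                             coverage_start = cov_start,
                             coverage_end = gap_at[gap] - 1L),
      data.table::data.table(person_id = persons$person_id[gap],
                             coverage_start = gap_at[gap] + gap_len[gap],
                             coverage_end = cov_end)))
    data.table::setorder(coverage, person_id, coverage_start)
    list(persons = persons, coverage = coverage)
  })
}

## Uniform random dates in [from, to].
rdate <- function(n, from, to) {
  from + as.integer(floor(runif(n) * (as.integer(to - from) + 1L)))
}

#' Generate multi-year diagnosis and dispensation histories
#'
#' For each person, latent condition flags are drawn independently from the
#' configured prevalences. Every flagged condition emits at least one mapped
#' ICD code inside the comorbidity year (physician claims when the condition
#' is detectable from a 3-digit ICD-9 code, hospital abstracts otherwise);
#' cohort-defining conditions additionally emit case-qualifying codes inside
#' the study window with probability `cohort_detect_prob`. Acute noise
#' diagnoses, drug dispensations (background plus condition-linked classes),
#' pregnancy-coded contacts, and post-admission complication diagnoses are
#' layered on top. Events outside a person's coverage intervals are dropped.
#'
#' @param registry output of [generate_registry()].
#' @param config the same [generator_config()].
#' @return list with `hospital` (one row per recorded diagnosis, keyed by
#'   admission), `physician`, `drugs`, and `truth` (latent flags; analysis
#'   modules must never read it).
#' @export
generate_history <- function(registry, config) {
  stopifnot(inherits(config, "generator_config"))
  persons <- registry$persons
  n <- nrow(persons)
  prevs <- config$condition_prevalences
  emis <- emission_codes()
  missing_emis <- setdiff(names(prevs), emis$condition)
  if (length(missing_emis))
    stop_config("condition_prevalences",
                paste("no bundled map entry for:", paste(missing_emis, collapse = ", ")))
  with_seed(config$seed + 202L, {
    ## latent flags
    flags <- sapply(names(prevs), function(cn) runif(n) < prevs[[cn]])
    if (is.null(dim(flags))) flags <- matrix(flags, nrow = n)
    colnames(flags) <- names(prevs)
    truth <- data.table::data.table(person_id = persons$person_id)
    for (cn in colnames(flags))
      data.table::set(truth, j = cn, value = as.integer(flags[, cn]))

    cy0 <- config$comorbidity_year[1]; cy1 <- config$comorbidity_year[2]
    hosp_dx <- list(); phys <- list(); drugs <- list()

    ## -- comorbidity-year condition emissions ------------------------------
    long <- data.table::melt(truth, id.vars = "person_id",
                             variable.name = "condition", value.name = "flag",
                             variable.factor = FALSE)
    long <- long[flag == 1L][, flag := NULL]
    long <- merge(long, emis, by = "condition", sort = FALSE)
    if (nrow(long)) {
      long[, n_events := 1L + rpois(.N, 0.3)]
      long[, via_phys := !is.na(icd9_3digit) &
             runif(.N) < config$physician_channel_prob]
      pl <- long[via_phys == TRUE]
      if (nrow(pl)) {
        pl <- pl[rep(seq_len(.N), n_events)]
        phys[["cond"]] <- data.table::data.table(
          person_id = pl$person_id,
          service_date = rdate(nrow(pl), cy0, cy1),
          diagnosis = pl$icd9_3digit)
      }
      hl <- long[via_phys == FALSE]
      if (nrow(hl)) {
        ## one admission per person carrying all hospital-channel condition
        ## codes as comorbid diagnoses; coding system chosen per admission,
        ## most responsible diagnosis drawn from the acute noise pool
        adm <- unique(hl[, .(person_id)])
        adm[, admission_date := rdate(.N, cy0, cy1 - 14L)]
        adm[, separation_date := admission_date + as.integer(floor(runif(.N) * 15))]
        adm[, use_icd10 := if (config$era_realism)
          admission_date >= as.Date("2002-04-01") else runif(.N) < 0.5]
        noise <- noise_code_pools()
        n9 <- noise[system == "ICD9"]$code
        n10 <- noise[system == "ICD10"]$code
        draw <- function(use10) data.table::fifelse(use10,
          n10[ceiling(runif(length(use10)) * length(n10))],
          n9[ceiling(runif(length(use10)) * length(n9))])
        adm[, mr_code := draw(use_icd10)]
        adm[, comp := runif(.N) < config$complication_dx_prob]
        adm[, comp_code := draw(use_icd10)]
        cond_rows <- adm[hl, on = "person_id"]
        cond_rows[, code := data.table::fifelse(use_icd10, icd10_code, icd9_code)]
        cond_rows <- cond_rows[!is.na(code)]
        sys_of <- function(dt) data.table::fifelse(dt$use_icd10, "ICD10", "ICD9")
        hosp_dx[["cond"]] <- data.table::rbindlist(list(
          adm[, .(person_id, admission_date, separation_date, code = mr_code,
                  system = sys_of(adm), dx_type = "most_responsible")],
          cond_rows[, .(person_id, admission_date, separation_date, code,
                        system = sys_of(cond_rows), dx_type = "comorbid")],
          adm[comp == TRUE][, .(person_id, admission_date, separation_date,
                                code = comp_code, system = sys_of(adm[comp == TRUE]),
                                dx_type = "post_admission_complication")]))
      }
    }

    ## -- study-window cohort-qualifying emissions --------------------------
    diab <- truth$person_id[
      (truth[["diabetes_uncomplicated"]] %||% 0L) == 1L |
      (truth[["diabetes_complicated"]] %||% 0L) == 1L]
    diab <- diab[runif(length(diab)) < config$cohort_detect_prob]
    sw0 <- config$study_window[1]; sw1 <- config$study_window[2]
    if (length(diab)) {
      via_hosp <- runif(length(diab)) < 0.4
      dh <- diab[via_hosp]
      if (length(dh)) {
        d0 <- rdate(length(dh), sw0, sw1 - 7L)
        use10 <- if (config$era_realism) d0 >= as.Date("2002-04-01")
                 else runif(length(dh)) < 0.5
        hosp_dx[["diab"]] <- data.table::data.table(
          person_id = dh, admission_date = d0, separation_date = d0 + 3L,
          code = ifelse(use10, "E11", "2500"),
          system = ifelse(use10, "ICD10", "ICD9"),
          dx_type = "comorbid")
      }
      dp <- diab[!via_hosp]
      if (length(dp)) {
        d1 <- rdate(length(dp), sw0, sw1 - 400L)
        d2 <- d1 + as.integer(30L + floor(runif(length(dp)) * 330))
        phys[["diab"]] <- data.table::data.table(
          person_id = c(dp, dp), service_date = c(d1, d2), diagnosis = "250")
      }
    }
    if ("osteoporosis" %in% names(prevs)) {
      ost <- truth$person_id[truth[["osteoporosis"]] == 1L]
      ost <- ost[runif(length(ost)) < config$cohort_detect_prob]
      if (length(ost)) {
        via_drug <- runif(length(ost)) < 0.5
        od <- ost[via_drug]
        if (length(od))
          drugs[["ost"]] <- data.table::data.table(
            person_id = od, dispense_date = rdate(length(od), sw0, sw1),
            ahfs_class = "92:24", ingredient = "alendronate")
        op <- ost[!via_drug]
        if (length(op))
          phys[["ost"]] <- data.table::data.table(
            person_id = op, service_date = rdate(length(op), sw0, sw1),
            diagnosis = "733")
      }
    }
    if ("pagets_disease" %in% names(prevs)) {
      ## Paget's is a 4-character rubric (731.0 / M88.x): not expressible in
      ## 3-digit physician claims, so it surfaces through hospital data.
      pag <- truth$person_id[truth[["pagets_disease"]] == 1L]
      if (length(pag)) {
        d0 <- rdate(length(pag), sw0, sw1 - 3L)
        use10 <- if (config$era_realism) d0 >= as.Date("2002-04-01")
                 else runif(length(pag)) < 0.5
        hosp_dx[["paget"]] <- data.table::data.table(
          person_id = pag, admission_date = d0, separation_date = d0 + 2L,
          code = ifelse(use10, "M880", "7310"),
          system = ifelse(use10, "ICD10", "ICD9"),
          dx_type = "comorbid")
      }
    }

    ## -- acute noise diagnoses (physician channel, comorbidity year) ------
    age_dec <- (age_at(persons$birth_date, config$outcome_year[1]) - 60) / 10
    mu <- config$noise_dx_mean * exp(0.25 * age_dec)
    n_noise <- rnbinom(n, size = config$noise_dx_size, mu = mu)
    truth[, n_noise_dx := n_noise]
    np9 <- noise_code_pools()[system == "ICD9"]$code
    idx <- rep(seq_len(n), n_noise)
    if (length(idx)) {
      codes <- np9[ceiling(runif(length(idx)) * length(np9))]
      nz <- data.table::data.table(
        person_id = persons$person_id[idx],
        service_date = rdate(length(idx), cy0, cy1),
        diagnosis = codes)
      ## distinct codes per person (burden counts distinct rubrics)
      nz <- unique(nz, by = c("person_id", "diagnosis"))
      phys[["noise"]] <- nz
      truth[, n_noise_dx := 0L]
      cnt <- nz[, .N, by = person_id]
      truth[cnt, n_noise_dx := i.N, on = "person_id"]
    }

    ## -- pregnancy/childbirth events (women 20-45) -------------------------
    agev <- age_at(persons$birth_date, config$outcome_year[1])
    fert <- persons$sex == "F" & agev >= 20 & agev <= 45
    preg <- fert & runif(n) < config$pregnancy_event_rate
    if (any(preg)) {
      pid <- persons$person_id[preg]
      phys[["preg"]] <- data.table::data.table(
        person_id = pid, service_date = rdate(length(pid), cy0, cy1),
        diagnosis = "650")
      deliver <- runif(length(pid)) < 0.5
      if (any(deliver)) {
        d0 <- rdate(sum(deliver), cy0, cy1 - 3L)
        use10 <- if (config$era_realism) d0 >= as.Date("2002-04-01")
                 else runif(sum(deliver)) < 0.5
        hosp_dx[["preg"]] <- data.table::data.table(
          person_id = pid[deliver], admission_date = d0,
          separation_date = d0 + 2L,
          code = ifelse(use10, "O80", "650"),
          system = ifelse(use10, "ICD10", "ICD9"),
          dx_type = "most_responsible")
      }
    }

    ## -- drug dispensations (comorbidity year) -----------------------------
    bg_pool <- background_drug_classes()
    n_bg <- rpois(n, config$drug_class_rate)
    idx <- rep(seq_len(n), n_bg)
    if (length(idx)) {
      cls <- bg_pool[ceiling(runif(length(idx)) * length(bg_pool))]
      bg <- data.table::data.table(
        person_id = persons$person_id[idx],
        dispense_date = rdate(length(idx), cy0, cy1),
        ahfs_class = cls, ingredient = NA_character_)
      drugs[["bg"]] <- unique(bg, by = c("person_id", "ahfs_class"))
    }
    links <- cds_condition_links()
    cds_classes <- load_cds_map()$classes
    linked <- long[condition %in% names(links)]
    if (nrow(linked)) {
      linked <- linked[runif(.N) < config$treat_prob]
      if (nrow(linked)) {
        linked[, cds_condition := links[condition]]
        cl <- merge(linked[, .(person_id, cds_condition)],
                    cds_classes[, .(cds_condition = condition, ahfs_class)],
                    by = "cds_condition", allow.cartesian = TRUE)
        ## one randomly chosen class per (person, cds condition)
        cl <- cl[, .SD[sample.int(.N, 1L)], by = .(person_id, cds_condition)]
        drugs[["linked"]] <- data.table::data.table(
          person_id = cl$person_id,
          dispense_date = rdate(nrow(cl), cy0, cy1),
          ahfs_class = cl$ahfs_class, ingredient = NA_character_)
      }
    }
    if ("osteoporosis" %in% names(prevs)) {
      osty <- truth$person_id[truth[["osteoporosis"]] == 1L]
      osty <- osty[runif(length(osty)) < config$treat_prob]
      if (length(osty))
        drugs[["ost_cy"]] <- data.table::data.table(
          person_id = osty, dispense_date = rdate(length(osty), cy0, cy1),
          ahfs_class = "92:24", ingredient = "alendronate")
    }

    hospital <- data.table::rbindlist(hosp_dx, use.names = TRUE, fill = TRUE)
    physician <- data.table::rbindlist(phys, use.names = TRUE)
    drugtab <- data.table::rbindlist(drugs, use.names = TRUE, fill = TRUE)
    if (!nrow(hospital))
      hospital <- data.table::data.table(
        person_id = character(), admission_date = as.Date(character()),
        separation_date = as.Date(character()), code = character(),
        system = character(), dx_type = character())
    if (!nrow(physician))
      physician <- data.table::data.table(
        person_id = character(), service_date = as.Date(character()),
        diagnosis = character())
    if (!nrow(drugtab))
      drugtab <- data.table::data.table(
        person_id = character(), dispense_date = as.Date(character()),
        ahfs_class = character(), ingredient = character())

    ## events only within coverage
    hospital <- filter_to_coverage(hospital, registry$coverage, "admission_date")
    physician <- filter_to_coverage(physician, registry$coverage, "service_date")
    drugtab <- filter_to_coverage(drugtab, registry$coverage, "dispense_date")
    data.table::setorder(hospital, person_id, admission_date)
    data.table::setorder(physician, person_id, service_date)
    data.table::setorder(drugtab, person_id, dispense_date)
    list(hospital = hospital, physician = physician, drugs = drugtab,
         truth = truth)
  })
}

## Keep only events whose date lies inside one of the person's coverage
## intervals.
filter_to_coverage <- function(events, coverage, date_col) {
  if (!nrow(events)) return(events)
  ev <- data.table::copy(events)
  ev[, `..d` := ev[[date_col]]]
  ## coverage intervals are non-overlapping: at most one match per event
  m <- coverage[ev, on = .(person_id, coverage_start <= ..d, coverage_end >= ..d),
                which = TRUE, mult = "first"]
  ev <- ev[!is.na(m)]
  ev[, `..d` := NULL]
  ev[]
}

#' Generate outcome-year deaths and hospitalizations from known models
#'
#' Death is Bernoulli on the inverse logit of the configured death
#' coefficients; hospitalization counts are Poisson on the exponentiated
#' log-linear predictor. Decedents get a death date uniform in the outcome
#' year, admissions after death are truncated, and generated abstracts carry
#' non-pregnancy (acute injury) diagnoses. A small share of women of
#' childbearing age additionally receives a pregnancy-coded admission, which
#' outcome derivation must exclude.
#'
#' @param registry output of [generate_registry()].
#' @param truth latent flags from [generate_history()].
#' @param config the same [generator_config()].
#' @return list with `persons` (registry persons with death dates filled),
#'   `hospital` (outcome-year abstracts) and `truth` (with generating linear
#'   predictors appended).
#' @export
generate_outcome_year <- function(registry, truth, config) {
  stopifnot(inherits(config, "generator_config"))
  persons <- data.table::copy(registry$persons)
  truth <- data.table::copy(truth)
  n <- nrow(persons)
  oy0 <- config$outcome_year[1]; oy1 <- config$outcome_year[2]
  with_seed(config$seed + 303L, {
    covars <- outcome_covariates(persons, truth, config)
    eta_d <- linear_predictor(covars, config$death_coefficients, "death_coefficients")
    eta_h <- linear_predictor(covars, config$hospitalization_coefficients,
                              "hospitalization_coefficients")
    p_death <- plogis_(eta_d)
    died <- runif(n) < p_death
    death_date <- rep(as.Date(NA), n)
    death_date[died] <- rdate(sum(died), oy0, oy1)
    persons[, death_date := ..death_date]
    lambda <- exp(eta_h)
    n_adm <- rpois(n, lambda)
    truth[, `:=`(eta_death = eta_d, p_death = p_death,
                 eta_hosp = eta_h, lambda_hosp = lambda)]

    idx <- rep(seq_len(n), n_adm)
    hosp <- list()
    if (length(idx)) {
      d0 <- rdate(length(idx), oy0, oy1 - 7L)
      keep <- is.na(death_date[idx]) | d0 <= death_date[idx]
      idx <- idx[keep]; d0 <- d0[keep]
      if (length(idx)) {
        noise <- noise_code_pools()
        use10 <- if (config$era_realism) rep(TRUE, length(idx))
                 else runif(length(idx)) < 0.5
        sys <- ifelse(use10, "ICD10", "ICD9")
        n9 <- noise[system == "ICD9"]$code; n10 <- noise[system == "ICD10"]$code
        mr <- ifelse(use10, n10[ceiling(runif(length(idx)) * length(n10))],
                     n9[ceiling(runif(length(idx)) * length(n9))])
        extra <- rpois(length(idx), 1.0)
        adm_id <- seq_along(idx)
        base <- data.table::data.table(
          person_id = persons$person_id[idx], admission_date = d0,
          separation_date = d0 + as.integer(floor(runif(length(idx)) * 8)),
          code = mr, system = sys, dx_type = "most_responsible",
          `..adm` = adm_id)
        ei <- rep(seq_along(idx), extra)
        if (length(ei)) {
          ec <- ifelse(use10[ei], n10[ceiling(runif(length(ei)) * length(n10))],
                       n9[ceiling(runif(length(ei)) * length(n9))])
          ext <- base[ei][, `:=`(code = ec, dx_type = "comorbid")]
          base <- rbind(base, ext)
        }
        data.table::setorder(base, `..adm`)
        base[, `..adm` := NULL]
        hosp[["main"]] <- base
      }
    }
    ## outcome-year pregnancy admissions (to be excluded downstream)
    agev <- age_at(persons$birth_date, oy0)
    fert <- persons$sex == "F" & agev >= 20 & agev <= 45 & is.na(death_date)
    preg <- fert & runif(n) < config$pregnancy_event_rate * 0.5
    if (any(preg)) {
      pid <- persons$person_id[preg]
      d0 <- rdate(length(pid), oy0, oy1 - 3L)
      use10 <- if (config$era_realism) rep(TRUE, length(pid))
               else runif(length(pid)) < 0.5
      hosp[["preg"]] <- data.table::data.table(
        person_id = pid, admission_date = d0, separation_date = d0 + 2L,
        code = ifelse(use10, "O80", "650"),
        system = ifelse(use10, "ICD10", "ICD9"),
        dx_type = "most_responsible")
    }
    hospital <- data.table::rbindlist(hosp, use.names = TRUE)
    if (!nrow(hospital))
      hospital <- data.table::data.table(
        person_id = character(), admission_date = as.Date(character()),
        separation_date = as.Date(character()), code = character(),
        system = character(), dx_type = character())
    data.table::setorder(hospital, person_id, admission_date)
    list(persons = persons, hospital = hospital, truth = truth)
  })
}

## Covariate matrix for the generating models; columns named to match
## coefficient names.
outcome_covariates <- function(persons, truth, config) {
  agev <- age_at(persons$birth_date, config$outcome_year[1])
  cond_cols <- intersect(names(config$condition_prevalences), names(truth))
  m <- cbind(
    `(Intercept)` = 1,
    age_dec = (agev - 60) / 10,
    male = as.numeric(persons$sex == "M"),
    burden = rowSums(as.matrix(truth[, ..cond_cols])) +
      (truth$n_noise_dx %||% 0L))
  for (cn in cond_cols) m <- cbind(m, stats::setNames(
    data.frame(truth[[cn]]), cn))
  m <- as.matrix(m)
  colnames(m)[5:ncol(m)] <- cond_cols
  m
}

linear_predictor <- function(covars, coefs, field) {
  bad <- setdiff(names(coefs), colnames(covars))
  if (length(bad))
    stop_config(field, paste("covariate(s) not available:",
                             paste(bad, collapse = ", ")))
  drop(covars[, names(coefs), drop = FALSE] %*% coefs)
}

#' Generate a complete linked claims bundle
#'
#' Runs [generate_registry()], [generate_history()] and
#' [generate_outcome_year()] under the config's seed and assembles the
#' linked tables. Identical (config, seed) yields an identical bundle.
#'
#' @param config a [generator_config()].
#' @return an object of class `claims_bundle`: a list with `registry`
#'   (persons incl. death dates), `coverage`, `hospital` (history and
#'   outcome-year abstracts, one row per recorded diagnosis), `physician`,
#'   `drugs`, and `truth`.
#' @export
generate_claims_bundle <- function(config = generator_config()) {
  reg <- generate_registry(config)
  hist <- generate_history(reg, config)
  out <- generate_outcome_year(reg, hist$truth, config)
  hospital <- data.table::rbindlist(list(hist$hospital, out$hospital),
                                    use.names = TRUE)
  data.table::setorder(hospital, person_id, admission_date)
  bundle <- structure(list(
    registry = out$persons, coverage = reg$coverage, hospital = hospital,
    physician = hist$physician, drugs = hist$drugs, truth = out$truth,
    comorbidity_year = config$comorbidity_year,
    outcome_year = config$outcome_year,
    study_window = config$study_window), class = "claims_bundle")
  validate_bundle(bundle)
  bundle
}

## Referential integrity: every person_id in event tables exists in registry.
validate_bundle <- function(bundle) {
  ids <- bundle$registry$person_id
  for (tb in c("coverage", "hospital", "physician", "drugs")) {
    orphan <- setdiff(unique(bundle[[tb]]$person_id), ids)
    if (length(orphan))
      stop("claims bundle integrity violation: ", length(orphan),
           " orphan person_id(s) in ", tb, call. = FALSE)
  }
  invisible(bundle)
}

#' Write a claims bundle as CSV tables
#'
#' Five analysis tables plus the truth table (with a `truth_` filename
#' prefix); UTF-8, header row, ISO-8601 dates.
#'
#' @param bundle a `claims_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite2 <- function(x, f) data.table::fwrite(x, file.path(dir, f),
                                               dateTimeAs = "ISO")
  fwrite2(bundle$registry, "registry.csv")
  fwrite2(bundle$coverage, "coverage.csv")
  fwrite2(bundle$hospital, "hospital.csv")
  fwrite2(bundle$physician, "physician.csv")
  fwrite2(bundle$drugs, "drugs.csv")
  fwrite2(bundle$truth, "truth_flags.csv")
  meta <- data.table::data.table(
    field = c("comorbidity_year_start", "comorbidity_year_end",
              "outcome_year_start", "outcome_year_end",
              "study_window_start", "study_window_end"),
    value = as.character(c(bundle$comorbidity_year, bundle$outcome_year,
                           bundle$study_window)))
  fwrite2(meta, "windows.csv")
  invisible(dir)
}

#' Read a claims bundle written by [write_bundle()]
#'
#' @param dir directory containing the CSV tables.
#' @return a `claims_bundle`.
#' @export
read_bundle <- function(dir) {
  rd <- function(f, dates) {
    x <- data.table::fread(file.path(dir, f))
    for (d in intersect(dates, names(x))) x[[d]] <- as_date(x[[d]])
    x
  }
  meta <- data.table::fread(file.path(dir, "windows.csv"))
  w <- function(k) as.Date(meta[field == k, value])
  truth_file <- file.path(dir, "truth_flags.csv")
  bundle <- structure(list(
    registry = rd("registry.csv", c("birth_date", "death_date")),
    coverage = rd("coverage.csv", c("coverage_start", "coverage_end")),
    hospital = rd("hospital.csv", c("admission_date", "separation_date")),
    physician = rd("physician.csv", "service_date"),
    drugs = rd("drugs.csv", "dispense_date"),
    truth = if (file.exists(truth_file)) data.table::fread(truth_file) else NULL,
    comorbidity_year = c(w("comorbidity_year_start"), w("comorbidity_year_end")),
    outcome_year = c(w("outcome_year_start"), w("outcome_year_end")),
    study_window = c(w("study_window_start"), w("study_window_end"))),
    class = "claims_bundle")
  validate_bundle(bundle)
  bundle
}
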