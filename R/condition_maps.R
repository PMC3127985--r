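# Condition mapping tables and ICD code matching.
#
# Diagnosis-based maps (Charlson, Elixhauser, cohort case definitions) ship
# as CSV with columns condition, system, pattern_type {prefix, range},
# pattern, weight, hierarchy_group, hierarchy_rank. Codes are normalized
# (uppercase, periods stripped) before matching; a `prefix` pattern matches
# any code it is a prefix of, and a `range` pattern "A-B" matches any code
# whose first nchar(A) characters fall lexicographically in [A, B].

#' Normalize ICD diagnosis codes
#'
#' Uppercases and strips periods and whitespace so that map patterns and
#' event codes compare on the same footing (e.g. "i50.0" -> "I500").
#'
#' @param x character vector of diagnosis codes.
#' @return normalized character vector.
#' @export
normalize_code <- function(x) {
  gsub("[. ]", "", toupper(trimws(as.character(x))))
}

#' Documented ordering of the 31 Elixhauser condition indicators
#'
#' The fixed order used for the indicator vector and for the expanded
#' design-matrix columns (most to least prevalent in a general adult
#' population).
#'
#' @return character vector of 31 condition names.
#' @export
elixhauser_conditions <- function() {
  c("hypertension_uncomplicated", "chronic_pulmonary_disease", "depression",
    "hypothyroidism", "solid_tumor", "congestive_heart_failure", "psychoses",
    "rheumatoid_arthritis", "diabetes_complicated", "valvular_disease",
    "other_neurological_disorders", "cardiac_arrhythmias",
    "fluid_electrolyte_disorders", "coagulopathy", "metastatic_cancer",
    "renal_failure", "drug_abuse", "peripheral_vascular_disease",
    "deficiency_anemia", "hypertension_complicated",
    "pulmonary_circulation_disorders", "liver_disease", "alcohol_abuse",
    "diabetes_uncomplicated", "obesity", "paralysis", "peptic_ulcer_disease",
    "lymphoma", "weight_loss", "blood_loss_anemia", "aids_hiv")
}

validate_diagnosis_map <- function(map, name) {
  need <- c("condition", "system", "pattern_type", "pattern")
  if (!all(need %in% names(map)))
    stop("malformed ", name, " map: missing columns ",
         paste(setdiff(need, names(map)), collapse = ", "), call. = FALSE)
  if (any(!nzchar(map$pattern)))
    stop("malformed ", name, " map: empty pattern", call. = FALSE)
  if (!all(map$system %in% c("ICD9", "ICD10")))
    stop("malformed ", name, " map: unknown coding system", call. = FALSE)
  if (!all(map$pattern_type %in% c("prefix", "range")))
    stop("malformed ", name, " map: unknown pattern_type", call. = FALSE)
  rng <- map[pattern_type == "range"]
  if (nrow(rng)) {
    parts <- strsplit(rng$pattern, "-", fixed = TRUE)
    ok <- vapply(parts, function(p)
      length(p) == 2L && nchar(p[1]) == nchar(p[2]) && p[1] <= p[2], logical(1))
    if (!all(ok))
      stop("malformed ", name, " map: bad range pattern(s): ",
           paste(rng$pattern[!ok], collapse = ", "), call. = FALSE)
  }
  invisible(map)
}

#' Load a bundled diagnosis condition map
#'
#' @param name one of `"charlson"`, `"elixhauser"`, `"cohort"`. The Charlson
#'   map carries 17 conditions with weights in \{1, 2, 3, 6\} and hierarchy
#'   groups (diabetes, liver, cancer); the Elixhauser map carries the 31
#'   indicator conditions; the cohort map carries the case-definition
#'   conditions (diabetes, osteoporosis, Paget's disease).
#' @return a `data.table` with class `condition_map`; patterns normalized.
#' @export
load_condition_map <- function(name = c("charlson", "elixhauser", "cohort")) {
  name <- match.arg(name)
  cached_table(paste0("condition_map_", name), build_condition_map(name))
}

build_condition_map <- function(name) {
  file <- switch(name,
    charlson   = "charlson_map.csv",
    elixhauser = "elixhauser_map.csv",
    cohort     = "cohort_conditions_map.csv")
  map <- data.table::fread(extdata_path(file), colClasses = list(
    character = c("condition", "system", "pattern_type", "pattern")))
  map[, pattern := normalize_code(pattern)]
  validate_diagnosis_map(map, name)
  if (name == "charlson") {
    conds <- unique(map$condition)
    if (length(conds) != 17L)
      stop("Charlson map must define exactly 17 conditions", call. = FALSE)
    w <- unique(map[, .(condition, weight)])
    if (anyNA(w$weight) || nrow(w) != 17L || !all(w$weight %in% c(1, 2, 3, 6)))
      stop("Charlson weights must be one value in {1,2,3,6} per condition",
           call. = FALSE)
  }
  if (name == "elixhauser") {
    conds <- unique(map$condition)
    if (length(conds) != 31L)
      stop("Elixhauser map must define exactly 31 conditions", call. = FALSE)
    if (!setequal(conds, elixhauser_conditions()))
      stop("Elixhauser map conditions do not match the documented set",
           call. = FALSE)
  }
  data.table::setattr(map, "map_name", name)
  data.table::setattr(map, "class", c("condition_map", class(map)))
  map[]
}

#' Match normalized codes against a condition map
#'
#' @param codes a `data.table` (or data.frame) with columns `system` and
#'   `code`; codes are normalized internally.
#' @param map a `condition_map`.
#' @return a `data.table` with columns `system`, `code`, `condition`, one row
#'   per (code, condition) match.
#' @export
match_codes <- function(codes, map) {
  codes <- data.table::as.data.table(codes)[, .(system, code)]
  codes <- unique(codes[, code := normalize_code(code)])
  out <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    sys <- map$system[i]; pat <- map$pattern[i]
    cand <- codes[system == sys]
    if (!nrow(cand)) next
    hit <- if (map$pattern_type[i] == "prefix") {
      startsWith(cand$code, pat)
    } else {
      ab <- strsplit(pat, "-", fixed = TRUE)[[1]]
      L <- nchar(ab[1])
      pre <- substr(cand$code, 1L, L)
      nchar(cand$code) >= L & pre >= ab[1] & pre <= ab[2]
    }
    if (any(hit))
      out[[i]] <- data.table::data.table(
        system = sys, code = cand$code[hit], condition = map$condition[i])
  }
  res <- data.table::rbindlist(out)
  if (!nrow(res))
    return(data.table::data.table(system = character(), code = character(),
                                  condition = character()))
  unique(res)
}

#' Condition hierarchy rules of a map
#'
#' Pairs (superior, inferior) where flagging the superior condition
#' suppresses the inferior one's score contribution: complicated diabetes
#' over uncomplicated, moderate/severe liver disease over mild, metastatic
#' tumor over non-metastatic malignancy.
#'
#' @param map a `condition_map` with hierarchy columns.
#' @return `data.table` with columns `superior`, `inferior`.
#' @export
hierarchy_rules <- function(map) {
  h <- unique(map[!is.na(hierarchy_rank) & nzchar(hierarchy_group),
                  .(condition, hierarchy_group, hierarchy_rank)])
  if (!nrow(h))
    return(data.table::data.table(superior = character(), inferior = character()))
  h[, {
    stopifnot(.N == 2L)  # bundled maps use two-level hierarchies
    o <- order(hierarchy_rank)
    .(superior = condition[o[2]], inferior = condition[o[1]])
  }, by = hierarchy_group][, .(superior, inferior)]
}

#' Load the bundled Chronic Disease Score table
#'
#' The CDS maps dispensed drug classes (two-level AHFS prefixes) to 17
#' chronic conditions and assigns each condition a score from 1 to 5,
#' tiered by the number of distinct matched classes for some conditions;
#' a `weak` class (diuretics under hypertension) earns only the reduced
#' weak-only score when no other class of that condition is present.
#'
#' @return a list with elements `classes` (condition, ahfs_class, weak) and
#'   `tiers` (condition, score_1, score_2, score_3, score_weak_only).
#' @export
load_cds_map <- function() {
  cached_table("cds_map", build_cds_map())
}

build_cds_map <- function() {
  classes <- data.table::fread(extdata_path("cds_classes.csv"), colClasses = list(
    character = c("condition", "ahfs_class", "label"), integer = "weak"))
  tiers <- data.table::fread(extdata_path("cds_tiers.csv"))
  conds <- unique(classes$condition)
  if (length(conds) != 17L || !setequal(conds, tiers$condition))
    stop("CDS table must define exactly 17 conditions", call. = FALSE)
  sc <- unlist(tiers[, .(score_1, score_2, score_3)])
  if (!all(sc %in% 1:5))
    stop("CDS scores must lie in 1..5", call. = FALSE)
  if (any(tiers$score_1 > tiers$score_2 | tiers$score_2 > tiers$score_3))
    stop("CDS tier scores must be non-decreasing in class count", call. = FALSE)
  maxima <- pmax(tiers$score_3, data.table::fifelse(
    is.na(tiers$score_weak_only), 0L, as.integer(tiers$score_weak_only)))
  if (sum(maxima) != 35L)
    stop("CDS per-condition maxima must sum to 35", call. = FALSE)
  list(classes = classes[, .(condition, ahfs_class, weak)], tiers = tiers)
}

#' Load the pregnancy/childbirth/abortion exclusion code set
#'
#' @return `data.table` with columns `system`, `pattern_type`, `pattern`.
#' @export
load_pregnancy_exclusions <- function() {
  cached_table("pregnancy_exclusions", {
    ex <- data.table::fread(extdata_path("pregnancy_exclusions.csv"),
                            colClasses = "character")
    ex[, pattern := normalize_code(pattern)]
    ex[, condition := "pregnancy"]
    validate_diagnosis_map(ex, "pregnancy-exclusion")
    ex[]
  })
}

#' Load the osteoprotective medication list
#'
#' Ingredient labels used by the osteoporosis case definition, with an AHFS
#' drug-class fallback for dispensations lacking an ingredient label.
#'
#' @return `data.table` with columns `ingredient`, `ahfs_class`.
#' @export
load_osteoporosis_drugs <- function() {
  cached_table("osteoporosis_drugs",
               data.table::fread(extdata_path("osteoporosis_drugs.csv"),
                                 colClasses = "character"))
}

## TRUE for codes that hit any pregnancy/childbirth/abortion pattern.
is_pregnancy_code <- function(system, code, exclusions = load_pregnancy_exclusions()) {
  dt <- data.table::data.table(system = system, code = normalize_code(code))
  m <- match_codes(dt, exclusions)
  dt[, paste(system, code) %in% m[, paste(system, code)]]
}
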