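# The five comorbidity measures, computed from one year of claims:
# distinct-diagnosis count, Charlson index, the 31 Elixhauser indicators,
# distinct drug-class count (capped at 125), and the Chronic Disease Score.

#' Assemble the diagnosis events eligible for comorbidity measurement
#'
#' Pools hospital and physician diagnoses inside the assessment window.
#' Pregnancy/childbirth/abortion codes are removed under both policies
#' (these contacts are not disease-related); hospital diagnoses typed as
#' post-admission complications are removed under `policy = "for_index"`
#' (Charlson/Elixhauser) and retained under `policy = "for_count"` (the
#' distinct-diagnosis count, where the printed exclusion applies only to
#' the index calculations).
#'
#' @param bundle a `claims_bundle`.
#' @param window two dates (the comorbidity fiscal year).
#' @param policy `"for_index"` or `"for_count"`.
#' @param person_id optional character vector restricting to some persons.
#' @return `data.table` with columns person_id, date, code (normalized),
#'   system, source, dx_type.
#' @export
filter_eligible_diagnoses <- function(bundle, window,
                                      policy = c("for_index", "for_count"),
                                      person_id = NULL) {
  policy <- match.arg(policy)
  window <- as_date(window)
  hosp <- bundle$hospital[admission_date >= window[1] &
                          admission_date <= window[2]]
  phys <- bundle$physician[service_date >= window[1] &
                           service_date <= window[2]]
  if (!is.null(person_id)) {
    ids <- person_id
    hosp <- hosp[hosp$person_id %in% ids]
    phys <- phys[phys$person_id %in% ids]
  }
  ev <- data.table::rbindlist(list(
    hosp[, .(person_id, date = admission_date, code = normalize_code(code),
             system, source = "hospital", dx_type)],
    phys[, .(person_id, date = service_date, code = normalize_code(diagnosis),
             system = "ICD9", source = "physician", dx_type = NA_character_)]))
  if (!nrow(ev)) return(ev)
  if (policy == "for_index")
    ev <- ev[is.na(dx_type) | dx_type != "post_admission_complication"]
  preg <- is_pregnancy_code(ev$system, ev$code)
  ev[!preg]
}

#' Count distinct diagnoses to the third character
#'
#' Number of distinct (coding system, first-three-character) pairs across
#' hospital and physician events. No cross-walk is attempted between ICD-9
#' and ICD-10: the same disease coded in both systems counts twice.
#'
#' @param events eligible events from [filter_eligible_diagnoses()] (policy
#'   `"for_count"`).
#' @return non-negative integer.
#' @export
count_distinct_diagnoses <- function(events) {
  if (!nrow(events)) return(0L)
  nrow(unique(data.table::data.table(system = events$system,
                                     code3 = substr(events$code, 1L, 3L))))
}

#' Flag map conditions present in a set of diagnosis events
#'
#' A condition is present iff at least one event code prefix-matches one of
#' its patterns in the event's coding system.
#'
#' @param events eligible events (policy `"for_index"` for the indices).
#' @param map a `condition_map`.
#' @return named logical vector over the map's conditions (file order; the
#'   documented indicator order for the Elixhauser map).
#' @export
match_conditions <- function(events, map) {
  conds <- if (identical(attr(map, "map_name"), "elixhauser"))
    elixhauser_conditions() else unique(map$condition)
  flags <- stats::setNames(rep(FALSE, length(conds)), conds)
  if (nrow(events)) {
    m <- match_codes(events[, .(system, code)], map)
    flags[unique(m$condition)] <- TRUE
  }
  flags
}

#' Charlson comorbidity index score
#'
#' Weighted sum (weights 1-6) over the 17 Charlson conditions after
#' hierarchy resolution: complicated diabetes suppresses uncomplicated
#' diabetes, moderate/severe liver disease suppresses mild liver disease,
#' and metastatic solid tumor suppresses non-metastatic malignancy. With
#' the bundled weights the attainable maximum after hierarchy resolution
#' is 29.
#'
#' @param flags named logical vector over the 17 Charlson conditions.
#' @param map the Charlson `condition_map`.
#' @return non-negative integer score.
#' @export
charlson_score <- function(flags, map = load_condition_map("charlson")) {
  w <- unique(map[, .(condition, weight)])
  if (length(flags) != nrow(w))
    stop("flag vector must cover the ", nrow(w), " Charlson conditions",
         call. = FALSE)
  if (is.null(names(flags))) names(flags) <- w$condition
  stopifnot(setequal(names(flags), w$condition))
  f <- flags
  h <- hierarchy_rules(map)
  for (i in seq_len(nrow(h)))
    if (isTRUE(f[[h$superior[i]]])) f[[h$inferior[i]]] <- FALSE
  as.integer(sum(w$weight[match(names(f)[f], w$condition)]))
}

#' Elixhauser indicator vector
#'
#' @param flags named logical vector over the 31 Elixhauser conditions.
#' @return integer vector of length 31 in \{0,1\}, ordered per
#'   [elixhauser_conditions()]. No summary score is computed: each
#'   indicator enters a model as its own variable.
#' @export
elixhauser_vector <- function(flags) {
  conds <- elixhauser_conditions()
  if (length(flags) != 31L)
    stop("flag vector must cover the 31 Elixhauser conditions", call. = FALSE)
  if (is.null(names(flags))) names(flags) <- conds
  stopifnot(setequal(names(flags), conds))
  stats::setNames(as.integer(flags[conds]), conds)
}

## Two-level ("four-digit") AHFS class prefix, e.g. "08:12:04" -> "08:12".
## Dispensations lacking a two-level prefix are rejected with a warning.
ahfs_two_level <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  ok <- vapply(parts, function(p) length(p) >= 2L && all(nzchar(p[1:2])),
               logical(1))
  if (any(!ok))
    warning(sum(!ok), " dispensation(s) lack a two-level AHFS class; rejected",
            call. = FALSE)
  out <- rep(NA_character_, length(x))
  out[ok] <- vapply(parts[ok], function(p) paste(p[1:2], collapse = ":"), "")
  out
}

#' Count distinct dispensed drug classes
#'
#' Number of different two-level ("four-digit") AHFS pharmacologic-
#' therapeutic classes dispensed inside the window, capped at 125.
#'
#' @param dispensations `data.table` with columns `dispense_date`,
#'   `ahfs_class` (a single person's rows).
#' @param window two dates.
#' @return integer in 0..125.
#' @export
count_drug_classes <- function(dispensations, window) {
  window <- as_date(window)
  d <- dispensations[dispense_date >= window[1] & dispense_date <= window[2]]
  if (!nrow(d)) return(0L)
  cls <- ahfs_two_level(d$ahfs_class)
  min(125L, length(unique(cls[!is.na(cls)])))
}

## Per-(person, condition) CDS scores for a long table of matched classes.
cds_condition_scores <- function(matched, tiers) {
  agg <- matched[, .(k = pmin(3L, data.table::uniqueN(ahfs_class)),
                     all_weak = all(weak == 1L)),
                 by = .(person_id, condition)]
  agg <- merge(agg, tiers, by = "condition", sort = FALSE)
  agg[, score := data.table::fifelse(
    all_weak & !is.na(score_weak_only), as.integer(score_weak_only),
    as.integer(ifelse(k == 1L, score_1, ifelse(k == 2L, score_2, score_3))))]
  agg[, .(person_id, condition, score)]
}

#' Chronic Disease Score
#'
#' Drugs dispensed inside the window are mapped to 17 chronic conditions by
#' their two-level AHFS class; each condition present contributes a score
#' of 1-5, tiered by the number of distinct matched classes for some
#' conditions (a diuretic-only profile earns the reduced hypertension
#' score), and the per-condition scores are summed (range 0-35).
#'
#' @param dispensations a single person's dispensation rows.
#' @param map the CDS table from [load_cds_map()].
#' @param window two dates.
#' @return non-negative integer.
#' @export
cds_score <- function(dispensations, map = load_cds_map(), window) {
  window <- as_date(window)
  d <- dispensations[dispense_date >= window[1] & dispense_date <= window[2]]
  if (!nrow(d)) return(0L)
  d <- data.table::copy(d)
  d[, ahfs2 := ahfs_two_level(ahfs_class)]
  d <- d[!is.na(ahfs2)]
  d[, person_id := "x"]
  matched <- merge(d[, .(person_id, ahfs_class = ahfs2)],
                   map$classes, by = "ahfs_class", allow.cartesian = TRUE)
  if (!nrow(matched)) return(0L)
  sc <- cds_condition_scores(matched, map$tiers)
  as.integer(sum(sc$score))
}

#' Build comorbidity profiles for every cohort member
#'
#' One row per member carrying all five measures; members with no claims in
#' the window get all-zero measures.
#'
#' @param bundle a `claims_bundle`.
#' @param cohort a `cohort`.
#' @param window two dates (default: the bundle's comorbidity year).
#' @return `data.table`: person_id, n_diagnoses, charlson,
#'   elix_01..elix_31 (ordered per [elixhauser_conditions()]), n_drugs, cds.
#' @export
build_profiles <- function(bundle, cohort, window = bundle$comorbidity_year) {
  ids <- cohort$members$person_id
  missing <- setdiff(ids, bundle$registry$person_id)
  if (length(missing))
    stop("integrity error: ", length(missing),
         " cohort member(s) missing from registry", call. = FALSE)
  window <- as_date(window)
  prof <- data.table::data.table(person_id = ids, key = "person_id")

  ## distinct-diagnosis count (complications retained)
  prof[, n_diagnoses := 0L]
  ev_count <- filter_eligible_diagnoses(bundle, window, "for_count",
                                        person_id = ids)
  if (nrow(ev_count)) {
    nd <- unique(ev_count[, .(person_id, system,
                              code3 = substr(code, 1L, 3L))])[, .N, by = person_id]
    prof[nd, n_diagnoses := i.N, on = "person_id"]
  }

  ## condition flags for the two diagnosis indices (complications excluded)
  ev_idx <- filter_eligible_diagnoses(bundle, window, "for_index",
                                      person_id = ids)
  ch_map <- load_condition_map("charlson")
  el_map <- load_condition_map("elixhauser")
  ch_flags <- person_condition_flags(ev_idx, ch_map, ids,
                                     unique(ch_map$condition))
  el_flags <- person_condition_flags(ev_idx, el_map, ids,
                                     elixhauser_conditions())

  ## Charlson: hierarchy resolution then weighted sum, vectorized
  w <- unique(ch_map[, .(condition, weight)])
  h <- hierarchy_rules(ch_map)
  F <- ch_flags
  for (i in seq_len(nrow(h)))
    F[, h$inferior[i]] <- F[, h$inferior[i]] & !F[, h$superior[i]]
  prof[, charlson := as.integer(F[, w$condition, drop = FALSE] %*% w$weight)]

  elix_cols <- sprintf("elix_%02d", 1:31)
  for (j in 1:31) prof[, (elix_cols[j]) := as.integer(el_flags[, j])]

  ## drug measures
  drugs <- bundle$drugs[person_id %in% ids & dispense_date >= window[1] &
                        dispense_date <= window[2]]
  prof[, n_drugs := 0L]
  prof[, cds := 0L]
  if (nrow(drugs)) {
    drugs <- data.table::copy(drugs)
    drugs[, ahfs2 := ahfs_two_level(ahfs_class)]
    drugs <- drugs[!is.na(ahfs2)]
    ndr <- unique(drugs[, .(person_id, ahfs2)])[, .(n = pmin(125L, .N)),
                                                by = person_id]
    prof[ndr, n_drugs := i.n, on = "person_id"]
    cdsm <- load_cds_map()
    matched <- merge(unique(drugs[, .(person_id, ahfs_class = ahfs2)]),
                     cdsm$classes, by = "ahfs_class", allow.cartesian = TRUE)
    if (nrow(matched)) {
      sc <- cds_condition_scores(matched, cdsm$tiers)
      tot <- sc[, .(cds = sum(score)), by = person_id]
      prof[tot, cds := i.cds, on = "person_id"]
    }
  }
  prof[]
}

## Person x condition logical flag matrix from eligible events.
person_condition_flags <- function(events, map, ids, cond_order) {
  F <- matrix(FALSE, nrow = length(ids), ncol = length(cond_order),
              dimnames = list(ids, cond_order))
  if (nrow(events)) {
    m <- match_codes(events[, .(system, code)], map)
    if (nrow(m)) {
      hit <- events[m, on = c("system", "code"), nomatch = NULL,
                    allow.cartesian = TRUE]
      hit <- unique(hit[, .(person_id, condition)])
      F[cbind(match(hit$person_id, ids), match(hit$condition, cond_order))] <- TRUE
    }
  }
  F
}

#' Write comorbidity profiles as CSV
#'
#' @param profiles output of [build_profiles()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_profiles <- function(profiles, file) {
  data.table::fwrite(profiles, file)
  invisible(file)
}
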