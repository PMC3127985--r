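# Independent brute-force oracles. These re-implement the scoring and
# evaluation semantics with plain loops and direct set arithmetic, sharing
# no code with the package implementations beyond the bundled data tables.

library(data.table)

## AUC by explicit enumeration of all case-control pairs.
auc_brute <- function(scores, y) {
  cases <- scores[y == 1]; ctrls <- scores[y == 0]
  tot <- 0
  for (a in cases) for (b in ctrls)
    tot <- tot + (if (a > b) 1 else if (a == b) 0.5 else 0)
  tot / (length(cases) * length(ctrls))
}

## Direct pattern matcher (loop over patterns).
matches_pattern_brute <- function(code, sys, map_rows) {
  for (i in seq_len(nrow(map_rows))) {
    if (map_rows$system[i] != sys) next
    pat <- map_rows$pattern[i]
    if (map_rows$pattern_type[i] == "prefix") {
      if (substr(code, 1, nchar(pat)) == pat) return(TRUE)
    } else {
      ab <- strsplit(pat, "-", fixed = TRUE)[[1]]
      L <- nchar(ab[1])
      if (nchar(code) >= L) {
        pre <- substr(code, 1, L)
        if (pre >= ab[1] && pre <= ab[2]) return(TRUE)
      }
    }
  }
  FALSE
}

norm_brute <- function(x) gsub("[. ]", "", toupper(x))

## All diagnosis events of one person in a window, as a plain data.frame.
person_events_brute <- function(bundle, pid, window, drop_complications) {
  h <- bundle$hospital[bundle$hospital$person_id == pid &
                       bundle$hospital$admission_date >= window[1] &
                       bundle$hospital$admission_date <= window[2], ]
  if (drop_complications) h <- h[h$dx_type != "post_admission_complication", ]
  p <- bundle$physician[bundle$physician$person_id == pid &
                        bundle$physician$service_date >= window[1] &
                        bundle$physician$service_date <= window[2], ]
  ev <- rbind(
    data.frame(code = norm_brute(h$code), system = h$system),
    data.frame(code = norm_brute(p$diagnosis),
               system = rep("ICD9", nrow(p))))
  if (!nrow(ev)) return(ev)
  preg <- load_pregnancy_exclusions()
  keep <- !vapply(seq_len(nrow(ev)), function(i)
    matches_pattern_brute(ev$code[i], ev$system[i], preg), logical(1))
  ev[keep, , drop = FALSE]
}

## All five measures for one person, by direct per-person computation.
profile_brute <- function(bundle, pid, window) {
  ev_count <- person_events_brute(bundle, pid, window, drop_complications = FALSE)
  n_dx <- if (nrow(ev_count))
    nrow(unique(data.frame(s = ev_count$system,
                           c3 = substr(ev_count$code, 1, 3)))) else 0L

  ev <- person_events_brute(bundle, pid, window, drop_complications = TRUE)
  flag_conditions <- function(map) {
    conds <- unique(map$condition)
    out <- setNames(rep(FALSE, length(conds)), conds)
    for (cn in conds) {
      rows <- map[map$condition == cn, ]
      for (i in seq_len(nrow(ev)))
        if (matches_pattern_brute(ev$code[i], ev$system[i], rows)) {
          out[cn] <- TRUE; break
        }
    }
    out
  }
  ch_map <- load_condition_map("charlson")
  chf <- flag_conditions(ch_map)
  ## hierarchy, spelled out
  if (chf[["diabetes_complicated"]]) chf[["diabetes_uncomplicated"]] <- FALSE
  if (chf[["moderate_severe_liver_disease"]]) chf[["mild_liver_disease"]] <- FALSE
  if (chf[["metastatic_solid_tumor"]]) chf[["malignancy"]] <- FALSE
  wts <- unique(as.data.frame(ch_map)[, c("condition", "weight")])
  charlson <- sum(wts$weight[match(names(chf)[chf], wts$condition)])

  elf <- flag_conditions(load_condition_map("elixhauser"))
  elix <- as.integer(elf[elixhauser_conditions()])

  d <- bundle$drugs[bundle$drugs$person_id == pid &
                    bundle$drugs$dispense_date >= window[1] &
                    bundle$drugs$dispense_date <= window[2], ]
  two_level <- character()
  for (cl in d$ahfs_class) {
    p <- strsplit(cl, ":", fixed = TRUE)[[1]]
    if (length(p) >= 2) two_level <- c(two_level, paste(p[1], p[2], sep = ":"))
  }
  two_level <- unique(two_level)
  n_drugs <- min(125L, length(two_level))

  cdsm <- load_cds_map()
  cds_total <- 0L
  for (cn in unique(cdsm$classes$condition)) {
    rows <- cdsm$classes[cdsm$classes$condition == cn, ]
    hit <- rows[rows$ahfs_class %in% two_level, ]
    if (!nrow(hit)) next
    tier <- cdsm$tiers[cdsm$tiers$condition == cn, ]
    if (all(hit$weak == 1L) && !is.na(tier$score_weak_only)) {
      cds_total <- cds_total + tier$score_weak_only
    } else {
      k <- min(3L, nrow(hit))
      cds_total <- cds_total + tier[[paste0("score_", k)]]
    }
  }
  list(n_diagnoses = n_dx, charlson = as.integer(charlson), elixhauser = elix,
       n_drugs = n_drugs, cds = as.integer(cds_total))
}

## Outcome derivation for one person, by direct logic.
outcome_brute <- function(bundle, pid, window) {
  r <- bundle$registry[bundle$registry$person_id == pid, ]
  death <- as.integer(!is.na(r$death_date) && r$death_date >= window[1] &&
                        r$death_date <= window[2])
  h <- bundle$hospital[bundle$hospital$person_id == pid &
                       bundle$hospital$admission_date >= window[1] &
                       bundle$hospital$admission_date <= window[2], ]
  preg <- load_pregnancy_exclusions()
  adms <- unique(h[, c("person_id", "admission_date")])
  n_adm <- 0L
  for (i in seq_len(nrow(adms))) {
    rows <- h[h$admission_date == adms$admission_date[i], ]
    mr <- rows[rows$dx_type == "most_responsible", ]
    excluded <- FALSE
    if (nrow(mr))
      excluded <- all(vapply(seq_len(nrow(mr)), function(j)
        matches_pattern_brute(norm_brute(mr$code[j]), mr$system[j], preg),
        logical(1)))
    if (!excluded) n_adm <- n_adm + 1L
  }
  list(death = death, n = n_adm,
       ge1 = as.integer(n_adm >= 1), ge2 = as.integer(n_adm >= 2))
}

## A tiny hand-assembled bundle for targeted unit tests.
manual_bundle <- function(registry, coverage = NULL, hospital = NULL,
                          physician = NULL, drugs = NULL) {
  empty_h <- data.table(person_id = character(),
                        admission_date = as.Date(character()),
                        separation_date = as.Date(character()),
                        code = character(), system = character(),
                        dx_type = character())
  empty_p <- data.table(person_id = character(),
                        service_date = as.Date(character()),
                        diagnosis = character())
  empty_d <- data.table(person_id = character(),
                        dispense_date = as.Date(character()),
                        ahfs_class = character(), ingredient = character())
  if (is.null(coverage))
    coverage <- data.table(person_id = registry$person_id,
                           coverage_start = as.Date("1995-04-01"),
                           coverage_end = as.Date("2003-03-31"))
  structure(list(
    registry = registry, coverage = coverage,
    hospital = if (is.null(hospital)) empty_h else hospital,
    physician = if (is.null(physician)) empty_p else physician,
    drugs = if (is.null(drugs)) empty_d else drugs,
    truth = NULL,
    comorbidity_year = as.Date(c("2001-04-01", "2002-03-31")),
    outcome_year = as.Date(c("2002-04-01", "2003-03-31")),
    study_window = as.Date(c("1996-04-01", "2002-03-31"))),
    class = "claims_bundle")
}

person_row <- function(id, birth = "1950-06-15", sex = "F", region = "urban",
                       quintile = 3L, death = NA) {
  data.table(person_id = id, birth_date = as.Date(birth), sex = sex,
             region = region, income_quintile = as.integer(quintile),
             death_date = as.Date(death))
}
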