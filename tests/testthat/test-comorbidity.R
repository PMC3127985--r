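cy <- as.Date(c("2001-04-01", "2002-03-31"))

test_that("eligible-diagnosis filtering applies the complication and pregnancy rules", {
  reg <- person_row("P1")
  hosp <- data.table::data.table(
    person_id = "P1", admission_date = as.Date("2001-06-01"),
    separation_date = as.Date("2001-06-05"),
    code = c("I50", "J96"), system = "ICD10",
    dx_type = c("comorbid", "post_admission_complication"))
  phys <- data.table::data.table(
    person_id = "P1", service_date = as.Date("2001-07-01"), diagnosis = "650")
  b <- manual_bundle(reg, hospital = hosp, physician = phys)
  idx <- filter_eligible_diagnoses(b, cy, "for_index")
  expect_equal(idx$code, "I50")    # complication and delivery code removed
  cnt <- filter_eligible_diagnoses(b, cy, "for_count")
  expect_setequal(cnt$code, c("I50", "J96"))  # complication retained
  ## empty window
  expect_equal(nrow(filter_eligible_diagnoses(
    b, as.Date(c("1997-04-01", "1998-03-31")), "for_index")), 0L)
})

test_that("distinct-diagnosis count truncates to three characters per system", {
  ev <- data.table::data.table(
    person_id = "P1", date = as.Date("2001-06-01"),
    code = c("I210", "I214", "410"),
    system = c("ICD10", "ICD10", "ICD9"),
    source = c("hospital", "hospital", "physician"),
    dx_type = NA_character_)
  expect_equal(count_distinct_diagnoses(ev), 2L)
  expect_equal(count_distinct_diagnoses(rbind(ev, ev)), 2L)
  expect_equal(count_distinct_diagnoses(ev[0]), 0L)
})

test_that("condition matching flags the Quan categories", {
  ev <- data.table::data.table(
    person_id = "P1", date = as.Date("2001-06-01"),
    code = c("I500", "410"), system = c("ICD10", "ICD9"),
    source = "hospital", dx_type = "comorbid")
  el <- match_conditions(ev, load_condition_map("elixhauser"))
  expect_true(el[["congestive_heart_failure"]])
  ch <- match_conditions(ev, load_condition_map("charlson"))
  expect_true(ch[["myocardial_infarction"]])
  expect_true(ch[["congestive_heart_failure"]])
  none <- match_conditions(ev[0], load_condition_map("charlson"))
  expect_false(any(none))
})

test_that("Charlson scoring sums weights after hierarchy resolution", {
  map <- load_condition_map("charlson")
  conds <- unique(map$condition)
  none <- setNames(rep(FALSE, 17), conds)
  expect_equal(charlson_score(none, map), 0L)
  f <- none; f["congestive_heart_failure"] <- TRUE
  f["metastatic_solid_tumor"] <- TRUE
  expect_equal(charlson_score(f, map), 7L)
  ## complicated diabetes suppresses uncomplicated: 2, not 3
  f <- none; f["diabetes_uncomplicated"] <- TRUE; f["diabetes_complicated"] <- TRUE
  expect_equal(charlson_score(f, map), 2L)
  ## metastatic suppresses malignancy: 6, not 8
  f <- none; f["malignancy"] <- TRUE; f["metastatic_solid_tumor"] <- TRUE
  expect_equal(charlson_score(f, map), 6L)
  expect_error(charlson_score(none[-1], map), "17")
})

test_that("Elixhauser vector keeps the documented order and length", {
  conds <- elixhauser_conditions()
  none <- setNames(rep(FALSE, 31), conds)
  expect_equal(sum(elixhauser_vector(none)), 0L)
  f <- none; f["hypertension_uncomplicated"] <- TRUE
  v <- elixhauser_vector(f)
  expect_length(v, 31L)
  expect_equal(unname(which(v == 1L)),
               match("hypertension_uncomplicated", conds))
  expect_error(elixhauser_vector(none[-1]), "31")
})

test_that("drug-class count uses two-level prefixes and caps at 125", {
  mk <- function(classes) data.table::data.table(
    person_id = "P1", dispense_date = as.Date("2001-06-01"),
    ahfs_class = classes, ingredient = NA_character_)
  expect_equal(count_drug_classes(mk(c("08:12", "08:12:04", "24:06")), cy), 2L)
  many <- sprintf("%02d:%02d", rep(1:13, each = 10), rep(1:10, 13))
  expect_equal(count_drug_classes(mk(many), cy), 125L)
  expect_equal(count_drug_classes(mk(character()), cy), 0L)
  expect_warning(count_drug_classes(mk(c("08", "24:06")), cy), "two-level")
})

test_that("CDS tiers score by distinct classes and weak-only profiles", {
  cdsm <- load_cds_map()
  mk <- function(classes) data.table::data.table(
    person_id = "P1", dispense_date = as.Date("2001-06-01"),
    ahfs_class = classes, ingredient = NA_character_)
  expect_equal(cds_score(mk(character()), cdsm, cy), 0L)
  ## one cardiac class -> 3; two -> 4; three -> 5
  expect_equal(cds_score(mk("24:04"), cdsm, cy), 3L)
  expect_equal(cds_score(mk(c("24:04", "20:12")), cdsm, cy), 4L)
  expect_equal(cds_score(mk(c("24:04", "20:12", "24:12")), cdsm, cy), 5L)
  ## diuretics alone score the weak hypertension tier
  expect_equal(cds_score(mk("40:28"), cdsm, cy), 1L)
  expect_equal(cds_score(mk(c("40:28", "24:08")), cdsm, cy), 2L)
  ## conditions sum; duplicated classes count once
  expect_equal(cds_score(mk(c("68:20", "68:20", "68:36")), cdsm, cy), 3L)
  ## every condition at its maximum tier reaches the printed ceiling
  all_classes <- cdsm$classes$ahfs_class
  expect_equal(cds_score(mk(all_classes), cdsm, cy), 35L)
})

test_that("profiles match an independent brute-force scorer exactly", {
  cfg <- generator_config(n_persons = 200, seed = 41)
  b <- generate_claims_bundle(cfg)
  coh <- build_general_cohort(b)
  pr <- build_profiles(b, coh)
  elix_cols <- sprintf("elix_%02d", 1:31)
  for (pid in coh$members$person_id) {
    o <- profile_brute(b, pid, b$comorbidity_year)
    row <- pr[person_id == pid]
    expect_equal(row$n_diagnoses, o$n_diagnoses, label = pid)
    expect_equal(row$charlson, o$charlson, label = pid)
    expect_equal(unname(unlist(row[, ..elix_cols])), o$elixhauser, label = pid)
    expect_equal(row$n_drugs, o$n_drugs, label = pid)
    expect_equal(row$cds, o$cds, label = pid)
  }
})

test_that("measures are monotone under event addition and invariant to duplication", {
  cfg <- generator_config(n_persons = 60, seed = 43)
  b <- generate_claims_bundle(cfg)
  coh <- build_general_cohort(b)
  pr <- build_profiles(b, coh)
  ## duplicate every event table row
  b2 <- b
  b2$hospital <- rbind(b$hospital, b$hospital)
  b2$physician <- rbind(b$physician, b$physician)
  b2$drugs <- rbind(b$drugs, b$drugs)
  pr2 <- build_profiles(b2, coh)
  expect_equal(pr, pr2)
  ## add a new diagnosis and a new dispensation to one member
  pid <- coh$members$person_id[1]
  b3 <- b
  b3$physician <- rbind(b$physician, data.table::data.table(
    person_id = pid, service_date = as.Date("2001-08-01"), diagnosis = "428"))
  b3$drugs <- rbind(b$drugs, data.table::data.table(
    person_id = pid, dispense_date = as.Date("2001-08-01"),
    ahfs_class = "24:04", ingredient = NA_character_))
  pr3 <- build_profiles(b3, coh)
  old <- pr[person_id == pid]; new <- pr3[person_id == pid]
  expect_gte(new$n_diagnoses, old$n_diagnoses)
  expect_gte(new$charlson, old$charlson)
  expect_gte(new$n_drugs, old$n_drugs)
  expect_gte(new$cds, old$cds)
})

test_that("members without claims get all-zero profiles and rows are conserved", {
  reg <- rbind(person_row("P1"), person_row("P2"))
  b <- manual_bundle(reg)
  coh <- build_general_cohort(b)
  pr <- build_profiles(b, coh)
  expect_equal(nrow(pr), 2L)
  expect_true(all(pr[, -1] == 0))
  empty <- coh; empty$members <- coh$members[0]
  expect_equal(nrow(build_profiles(b, empty)), 0L)
})
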