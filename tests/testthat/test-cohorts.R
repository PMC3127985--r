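cover <- function(id, from, to)
  data.table::data.table(person_id = id, coverage_start = as.Date(from),
                         coverage_end = as.Date(to))

test_that("coverage predicate: superset interval, gaps, and death handling", {
  period <- as.Date(c("2001-04-01", "2003-03-31"))
  expect_true(has_continuous_coverage(
    cover("a", "2000-01-01", "2004-01-01"), period))
  ## a one-day gap inside the period disqualifies
  split <- rbind(cover("a", "2000-01-01", "2002-05-31"),
                 cover("a", "2002-06-02", "2004-01-01"))
  expect_false(has_continuous_coverage(split, period))
  ## exactly adjacent intervals do not
  adj <- rbind(cover("a", "2000-01-01", "2002-05-31"),
               cover("a", "2002-06-01", "2004-01-01"))
  expect_true(has_continuous_coverage(adj, period))
  ## coverage ending at an in-period death still qualifies
  expect_true(has_continuous_coverage(
    cover("a", "2000-01-01", "2002-09-15"), period,
    death_date = as.Date("2002-09-15")))
  expect_false(has_continuous_coverage(
    cover("a", "2000-01-01", "2002-09-15"), period))
})

test_that("general cohort applies the inclusive age-20 boundary", {
  reg <- rbind(person_row("P1", birth = "1982-04-02"),   # 19 at 2002-04-01
               person_row("P2", birth = "1982-04-01"),   # exactly 20
               person_row("P3", birth = "1950-01-01"))
  b <- manual_bundle(reg)
  coh <- build_general_cohort(b)
  expect_setequal(coh$members$person_id, c("P2", "P3"))
  expect_true(all(is.na(coh$members$index_date)))
})

test_that("diabetes case definition: hospital, single-claim, and 730-day rules", {
  reg <- rbind(person_row("H1"), person_row("P1"), person_row("P2"),
               person_row("P3"))
  hosp <- data.table::data.table(
    person_id = "H1", admission_date = as.Date("1999-05-01"),
    separation_date = as.Date("1999-05-04"), code = "E11", system = "ICD10",
    dx_type = "comorbid")
  phys <- data.table::data.table(
    person_id = c("P1", "P2", "P2", "P3", "P3"),
    service_date = as.Date(c("2000-01-01",
                             "1998-01-01", "2000-07-05",   # 2.5 years apart
                             "1999-01-01", "2000-06-01")), # within 730 days
    diagnosis = "250")
  b <- manual_bundle(reg, hospital = hosp, physician = phys)
  coh <- build_diabetes_cohort(b)
  ## one hospital record qualifies even as a comorbid diagnosis
  expect_true("H1" %in% coh$members$person_id)
  ## one claim alone does not; two claims 2.5 years apart do not
  expect_false("P1" %in% coh$members$person_id)
  expect_false("P2" %in% coh$members$person_id)
  expect_true("P3" %in% coh$members$person_id)
  expect_equal(coh$members[person_id == "P3", index_date],
               as.Date("1999-01-01"))
  expect_equal(coh$members[person_id == "H1", index_date],
               as.Date("1999-05-01"))
})

test_that("osteoporosis cohort: diagnosis or drug pathway, Paget exclusion", {
  reg <- rbind(person_row("D1", birth = "1940-01-01"),
               person_row("R1", birth = "1940-01-01"),
               person_row("PG", birth = "1940-01-01"),
               person_row("Y1", birth = "1960-01-01"))  # 42: below age floor
  phys <- data.table::data.table(
    person_id = c("D1", "PG", "Y1"),
    service_date = as.Date(c("1999-03-01", "1999-03-01", "1999-03-01")),
    diagnosis = "733")
  hosp <- data.table::data.table(
    person_id = "PG", admission_date = as.Date("2000-01-01"),
    separation_date = as.Date("2000-01-02"), code = "M880", system = "ICD10",
    dx_type = "comorbid")
  drugs <- data.table::data.table(
    person_id = "R1", dispense_date = as.Date("2001-06-01"),
    ahfs_class = "92:24", ingredient = "alendronate")
  b <- manual_bundle(reg, hospital = hosp, physician = phys, drugs = drugs)
  coh <- build_osteoporosis_cohort(b)
  expect_true("D1" %in% coh$members$person_id)
  ## drug dispensation alone qualifies
  expect_true("R1" %in% coh$members$person_id)
  expect_equal(coh$members[person_id == "R1", index_date],
               as.Date("2001-06-01"))
  ## Paget diagnosis excludes despite a qualifying osteoporosis code
  expect_false("PG" %in% coh$members$person_id)
  ## age floor of 50
  expect_false("Y1" %in% coh$members$person_id)
})

test_that("age restriction is an inclusive-65 partition", {
  cfg <- generator_config(n_persons = 600, seed = 4)
  b <- generate_claims_bundle(cfg)
  coh <- build_general_cohort(b)
  r65 <- restrict_age(coh, 65L)
  expect_true(all(r65$members$age_at_reference >= 65))
  dropped <- coh$members[!person_id %in% r65$members$person_id]
  expect_true(all(dropped$age_at_reference < 65))
  expect_equal(nrow(r65$members) + nrow(dropped), nrow(coh$members))
})

test_that("disease cohorts are subsets of the general cohort up to age floors", {
  cfg <- generator_config(n_persons = 4000, seed = 19)
  b <- generate_claims_bundle(cfg)
  gen <- build_general_cohort(b)
  dia <- build_diabetes_cohort(b)
  ost <- build_osteoporosis_cohort(b)
  expect_gt(nrow(dia$members), 0)
  expect_gt(nrow(ost$members), 0)
  expect_true(all(dia$members$person_id %in% gen$members$person_id))
  expect_true(all(ost$members$person_id %in% gen$members$person_id))
})

test_that("cohort inclusion agrees with a brute-force per-person re-check", {
  cfg <- generator_config(n_persons = 700, seed = 23, coverage_gap_fraction = 0.15)
  b <- generate_claims_bundle(cfg)
  coh <- build_general_cohort(b)
  spec <- cohort_spec("general")
  expected <- vapply(seq_len(nrow(b$registry)), function(i) {
    r <- b$registry[i]
    yb <- as.integer(format(r$birth_date, "%Y"))
    ya <- as.integer(format(spec$as_of_date, "%Y"))
    mdb <- format(r$birth_date, "%m%d"); mda <- format(spec$as_of_date, "%m%d")
    age <- ya - yb - as.integer(mda < mdb)
    alive <- is.na(r$death_date) || r$death_date >= spec$as_of_date
    cov <- has_continuous_coverage(b$coverage[person_id == r$person_id],
                                   spec$coverage_period, r$death_date)
    age >= 20L && alive && cov
  }, logical(1))
  expect_setequal(coh$members$person_id, b$registry$person_id[expected])
})

test_that("raising diabetes code prevalence grows the diabetes cohort", {
  lo <- default_condition_prevalences(); lo["diabetes_uncomplicated"] <- 0.02
  hi <- lo; hi["diabetes_uncomplicated"] <- 0.10
  b_lo <- generate_claims_bundle(generator_config(n_persons = 4000, seed = 37,
                                                  condition_prevalences = lo))
  b_hi <- generate_claims_bundle(generator_config(n_persons = 4000, seed = 37,
                                                  condition_prevalences = hi))
  expect_gt(nrow(build_diabetes_cohort(b_hi)$members),
            nrow(build_diabetes_cohort(b_lo)$members))
})
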