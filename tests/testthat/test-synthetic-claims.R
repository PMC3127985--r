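test_that("identical config and seed reproduce the bundle exactly", {
  cfg <- generator_config(n_persons = 500, seed = 7)
  b1 <- generate_claims_bundle(cfg)
  b2 <- generate_claims_bundle(cfg)
  for (tb in c("registry", "coverage", "hospital", "physician", "drugs", "truth"))
    expect_identical(b1[[tb]], b2[[tb]], label = tb)
})

test_that("degenerate proportions are honoured", {
  cfg <- generator_config(n_persons = 200, seed = 3, female_fraction = 1)
  reg <- generate_registry(cfg)
  expect_true(all(reg$persons$sex == "F"))
  expect_equal(nrow(reg$persons), 200L)
})

test_that("zero prevalences and zero drug rate give empty event tables", {
  prev <- default_condition_prevalences()
  prev[] <- 0
  cfg <- generator_config(n_persons = 300, seed = 5,
                          condition_prevalences = prev, drug_class_rate = 0,
                          pregnancy_event_rate = 0, noise_dx_mean = 0,
                          hospitalization_coefficients = c("(Intercept)" = -30))
  b <- generate_claims_bundle(cfg)
  expect_equal(nrow(b$physician), 0L)
  expect_equal(nrow(b$drugs), 0L)
  expect_equal(nrow(b$hospital), 0L)
})

test_that("a prevalence of one flags every person via mapped codes", {
  prev <- default_condition_prevalences()
  prev[] <- 0
  prev["congestive_heart_failure"] <- 1
  cfg <- generator_config(n_persons = 150, seed = 9,
                          condition_prevalences = prev,
                          coverage_gap_fraction = 0)
  b <- generate_claims_bundle(cfg)
  coh <- build_general_cohort(b)
  pr <- build_profiles(b, coh)
  chf_col <- sprintf("elix_%02d", match("congestive_heart_failure",
                                        elixhauser_conditions()))
  expect_true(all(pr[[chf_col]] == 1L))
})

test_that("income quintiles are near-uniform at large n", {
  cfg <- generator_config(n_persons = 50000, seed = 13, quintile_missing = 0)
  reg <- generate_registry(cfg)
  freq <- table(reg$persons$income_quintile) / nrow(reg$persons)
  se <- sqrt(0.2 * 0.8 / nrow(reg$persons))
  expect_true(all(abs(freq - 0.2) < 3 * se))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(generator_config(n_persons = -1), "n_persons")
  expect_error(generator_config(female_fraction = 1.4), "female_fraction")
  expect_error(generator_config(study_window = as.Date(c("2002-01-01", "2001-01-01"))),
               "study_window")
  expect_error(generator_config(condition_prevalences = c(not_a_condition = 0.1)),
               "unknown condition")
  expect_error(generator_config(death_coefficients = c(banana = 1)),
               "death_coefficients")
})

test_that("every event table is referentially intact and inside coverage", {
  cfg <- generator_config(n_persons = 800, seed = 21, coverage_gap_fraction = 0.3)
  b <- generate_claims_bundle(cfg)
  ids <- b$registry$person_id
  expect_true(all(b$hospital$person_id %in% ids))
  expect_true(all(b$physician$person_id %in% ids))
  expect_true(all(b$drugs$person_id %in% ids))
  ## history events fall inside a coverage interval of their person
  chk <- comorbibench:::filter_to_coverage(b$physician, b$coverage,
                                           "service_date")
  expect_equal(nrow(chk), nrow(b$physician))
})

test_that("removing the truth table changes no downstream output", {
  cfg <- generator_config(n_persons = 400, seed = 17)
  b <- generate_claims_bundle(cfg)
  b2 <- b
  b2$truth <- NULL
  coh <- build_general_cohort(b); coh2 <- build_general_cohort(b2)
  expect_identical(coh$members, coh2$members)
  expect_identical(build_profiles(b, coh), build_profiles(b2, coh2))
  expect_identical(derive_outcomes(b, coh), derive_outcomes(b2, coh2))
})

test_that("intercept-only death model is calibrated to its rate", {
  prev <- default_condition_prevalences()
  prev[] <- 0
  p0 <- 0.013
  cfg <- generator_config(
    n_persons = 100000, seed = 29, condition_prevalences = prev,
    drug_class_rate = 0, noise_dx_mean = 0, pregnancy_event_rate = 0,
    death_coefficients = c("(Intercept)" = stats::qlogis(p0)),
    hospitalization_coefficients = c("(Intercept)" = -30))
  b <- generate_claims_bundle(cfg)
  rate <- mean(!is.na(b$registry$death_date))
  se <- sqrt(p0 * (1 - p0) / cfg$n_persons)
  expect_lt(abs(rate - p0), 3 * se)
})

test_that("death risk is monotone across Charlson strata under a positive effect", {
  cfg <- generator_config(n_persons = 30000, seed = 31)
  b <- generate_claims_bundle(cfg)
  coh <- build_general_cohort(b)
  pr <- build_profiles(b, coh)
  oc <- derive_outcomes(b, coh)
  m <- merge(pr[, .(person_id, charlson)], oc[, .(person_id, death)],
             by = "person_id")
  m[, stratum := pmin(charlson, 2L)]
  rates <- m[, mean(death), keyby = stratum]$V1
  expect_true(all(diff(rates) >= 0))
})

test_that("bundles round-trip through CSV", {
  cfg <- generator_config(n_persons = 120, seed = 2)
  b <- generate_claims_bundle(cfg)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "truth_flags.csv")))
  b2 <- read_bundle(dir)
  coh <- build_general_cohort(b); coh2 <- build_general_cohort(b2)
  expect_equal(coh$members, coh2$members)
  expect_equal(build_profiles(b, coh), build_profiles(b2, coh2))
})
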