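test_that("c-statistic equals pair enumeration on canonical examples", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(c_statistic(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  y <- rep(c(0, 1), 5)
  expect_equal(c_statistic(y, y), 1.0)
  expect_error(c_statistic(1:4, c(1, 1, 1, 1)), "single class")
})

test_that("c-statistic matches brute force on random tied data", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(10:120, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    expect_equal(c_statistic(s, y), auc_brute(s, y), tolerance = 1e-12)
  }
})

test_that("DeLong interval behaves at the edges and agrees with pROC", {
  y <- rep(c(1, 0), each = 25)
  s <- c(stats::rnorm(25, 2), stats::rnorm(25))
  ## perfect separation: zero placement variance, degenerate interval
  perf <- delong_ci(y + 0, y)
  expect_equal(perf$c, 1); expect_equal(perf$ci_low, 1)
  expect_equal(perf$var, 0)
  ci <- delong_ci(s, y)
  expect_true(ci$ci_low >= 0 && ci$ci_high <= 1 &&
                ci$ci_low <= ci$c && ci$c <= ci$ci_high)
  ref <- suppressMessages(pROC::ci.auc(pROC::roc(y, s, quiet = TRUE),
                                       method = "delong"))
  expect_equal(ci$ci_low, as.numeric(ref[1]), tolerance = 1e-10)
  expect_equal(ci$c, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(ci$ci_high, as.numeric(ref[3]), tolerance = 1e-10)
  expect_error(delong_ci(c(1, 2, 3), c(1, 0, 0)), "at least 2")
})

test_that("DeLong paired test: identity, antisymmetry, and pROC agreement", {
  set.seed(202)
  n <- 150
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(x))
  a <- x + stats::rnorm(n)
  b <- x + stats::rnorm(n, sd = 0.5)
  same <- delong_paired_test(a, a, y)
  expect_equal(same$delta_c, 0); expect_equal(same$p, 1)
  fwd <- delong_paired_test(a, b, y)
  rev <- delong_paired_test(b, a, y)
  expect_equal(fwd$z, -rev$z)
  expect_equal(fwd$p, rev$p)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(abs(fwd$z), abs(as.numeric(ref$statistic)), tolerance = 1e-10)
  expect_equal(fwd$p, as.numeric(ref$p.value), tolerance = 1e-10)
})

test_that("DeLong paired p agrees with a paired-bootstrap oracle", {
  set.seed(303)
  n <- 300
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(0.8 * x))
  a <- x + stats::rnorm(n, sd = 1.2)
  b <- x + stats::rnorm(n, sd = 1.0)
  p_delong <- delong_paired_test(a, b, y)$p
  B <- 5000
  deltas <- vapply(seq_len(B), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    c_statistic(b[idx], y[idx]) - c_statistic(a[idx], y[idx])
  }, numeric(1))
  deltas <- deltas[!is.na(deltas)]
  p_boot <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  expect_lt(abs(p_delong - min(1, p_boot)), 0.02)
})

test_that("Brier score and SD follow the squared-error definitions", {
  expect_equal(brier(rep(0.5, 8), rbinom(8, 1, 0.5))$score, 0.25)
  y <- c(1, 0, 1, 1, 0)
  exact <- brier(y, y)
  expect_equal(exact$score, 0); expect_equal(exact$sd, 0)
  b <- brier(c(0.8, 0.2), c(1, 0))
  expect_equal(b$score, 0.04)
  expect_equal(b$sd, stats::sd(c(0.04, 0.04)))
  expect_error(brier(c(0.5, 0.5), c(1)), "length")
  expect_error(brier(c(1.2, 0.5), c(1, 0)), "0, 1")
})

test_that("Hosmer-Lemeshow: perfect calibration, df, and a hand-worked case", {
  set.seed(404)
  p <- rep(c(0.2, 0.6), each = 30)
  y <- c(rbinom(30, 1, 0.2), rbinom(30, 1, 0.6))
  ## force observed = expected within each group
  y[1:30] <- rep(0, 30); y[1:6] <- 1              # 6/30 = 0.2
  y[31:60] <- rep(0, 30); y[31:48] <- 1           # 18/30 = 0.6
  perfect <- hosmer_lemeshow(p, y, groups = 2)
  expect_equal(perfect$chi2, 0, tolerance = 1e-12)
  ten <- hosmer_lemeshow(stats::runif(200), rbinom(200, 1, 0.5), groups = 10)
  expect_equal(ten$df, 8L)
  ## hand-worked two-group example
  p2 <- c(0.1, 0.2, 0.7, 0.8); y2 <- c(0, 1, 1, 1)
  hw <- hosmer_lemeshow(p2, y2, groups = 2)
  e1 <- 0.3; o1 <- 1; e2 <- 1.5; o2 <- 2
  chi_manual <- (o1 - e1)^2 / (e1 * (1 - e1 / 2)) +
    (o2 - e2)^2 / (e2 * (1 - e2 / 2))
  expect_equal(hw$chi2, chi_manual)
  expect_error(hosmer_lemeshow(c(0.1, 0.9), c(0, 1), groups = 10), "at least")
})

test_that("McNemar handles symmetry, the exact fallback, and no discordance", {
  a <- c(rep(1, 10), rep(0, 10)); b <- c(rep(0, 5), rep(1, 5), rep(1, 5), rep(0, 5))
  m0 <- mcnemar(a, b)         # b = c = 5
  expect_equal(m0$chi2, 0)
  expect_equal(m0$method, "exact_binomial")
  a1 <- c(rep(1, 10), rep(0, 2), rep(1, 5)); b1 <- c(rep(0, 10), rep(1, 2), rep(1, 5))
  m1 <- mcnemar(a1, b1)       # b = 10, c = 2
  expect_equal(m1$chi2, 64 / 12)
  same <- rep(c(0, 1), 6)
  expect_equal(mcnemar(same, same)$method, "no_discordance")
  ## large-sample branch matches the uncorrected chi-square test
  set.seed(505)
  a2 <- rbinom(400, 1, 0.5); b2 <- rbinom(400, 1, 0.5)
  m2 <- mcnemar(a2, b2)
  ref <- stats::mcnemar.test(table(a2, b2), correct = FALSE)
  expect_equal(m2$chi2, unname(ref$statistic))
  expect_equal(m2$p, ref$p.value)
})

test_that("logistic fitting honours its contracts", {
  y <- rep(c(0, 1), 50)
  X <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_logistic(X, y)
  expect_equal(f$coefficients$estimate, 0, tolerance = 1e-8)
  expect_error(fit_logistic(X, rep(1, 100)), "constant")
  ## collinear column pruned with a warning
  X2 <- cbind(X, a = rep(1, 100))
  expect_warning(f2 <- fit_logistic(X2, y), "collinear")
  expect_equal(f2$coefficients$term, "(Intercept)")
  ## perfect separation detected
  x <- c(rep(-2, 50), rep(2, 50))
  ys <- as.integer(x > 0)
  expect_error(fit_logistic(cbind(X, sep = x), ys), "separation")
  ## recovery of known coefficients
  set.seed(606)
  n <- 4000
  Z <- cbind(`(Intercept)` = 1, z1 = rnorm(n), z2 = rbinom(n, 1, 0.3))
  beta <- c(-1, 0.8, -0.5)
  yr <- rbinom(n, 1, stats::plogis(Z %*% beta))
  fr <- fit_logistic(Z, yr)
  expect_true(all(abs(fr$coefficients$estimate - beta) <
                    3 * fr$coefficients$se))
})

test_that("the design matrix encodes the base model as documented", {
  members <- data.table::data.table(
    person_id = c("A", "B", "C"), index_date = as.Date(NA),
    age_at_reference = c(50L, 70L, 30L), sex = c("F", "M", "F"),
    region = c("urban", "rural", "missing"),
    income_quintile = c(1L, NA_integer_, 4L))
  prof <- data.table::data.table(person_id = c("A", "B", "C"),
                                 n_diagnoses = c(2L, 0L, 5L),
                                 charlson = 0L, n_drugs = 0L, cds = 0L)
  for (j in sprintf("elix_%02d", 1:31))
    prof[, (j) := c(0L, 1L, 0L)]
  dm <- suppressWarnings(
    build_design_matrix(prof, members, model_spec("death", "none")))
  expect_equal(unname(dm$X[, "age_sq"]), c(2500, 4900, 900))
  expect_equal(unname(dm$X[, "quintile_missing"]), c(0, 1, 0))
  expect_equal(unname(dm$X[, "region_missing"]), c(0, 0, 1))
  ## elixhauser term expands to 31 columns on top of the 11 base columns
  dme <- suppressWarnings(
    build_design_matrix(prof, members, model_spec("death", "elixhauser_31")))
  expect_equal(length(dme$dropped) + ncol(dme$X), 11L + 31L)
  ## continuous term enters as one column
  dmc <- suppressWarnings(
    build_design_matrix(prof, members, model_spec("death", "n_diagnoses")))
  expect_true("n_diagnoses" %in% colnames(dmc$X))
})

test_that("evaluate_measures reports six models per outcome within ranges", {
  cfg <- generator_config(n_persons = 3000, seed = 51)
  b <- generate_claims_bundle(cfg)
  coh <- build_general_cohort(b)
  pr <- build_profiles(b, coh)
  oc <- derive_outcomes(b, coh)
  res <- evaluate_measures(coh, pr, oc, outcomes_used = "hosp_ge1")
  expect_equal(nrow(res), 6L)
  expect_setequal(res$model, c("base", "n_diagnoses", "charlson",
                               "elixhauser_31", "n_drugs", "cds"))
  expect_true(all(res$c >= 0 & res$c <= 1))
  expect_true(all(res$brier >= 0 & res$brier <= 1))
  expect_true(all(is.na(res[model == "base", delta_c])))
  expect_true(all(!is.na(res[model != "base", delta_c])))
  expect_true(all(res$ci_low <= res$c & res$c <= res$ci_high))
})
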