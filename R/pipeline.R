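# End-to-end pipeline: generate -> cohorts -> comorbidity profiles ->
# outcomes -> evaluation, with report tables and a machine-readable run
# manifest. Deterministic given the generator seed.

#' Pipeline run configuration
#'
#' @param generator a [generator_config()].
#' @param cohort_labels which cohorts to build.
#' @param age_restricted also evaluate the 65+ restriction of each cohort.
#' @param hl_groups,ci_level evaluation options.
#' @param outcomes_used which outcomes to evaluate.
#' @param write_bundle also persist the generated claims tables.
#' @param verbose log per-stage progress and timing.
#' @return list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       cohort_labels = c("general", "diabetes", "osteoporosis"),
                       age_restricted = TRUE,
                       hl_groups = 10L, ci_level = 0.95,
                       outcomes_used = c("death", "hosp_ge1", "hosp_ge2"),
                       write_bundle = FALSE,
                       verbose = TRUE) {
  stopifnot(inherits(generator, "generator_config"))
  cohort_labels <- match.arg(cohort_labels, several.ok = TRUE)
  structure(list(generator = generator, cohort_labels = cohort_labels,
                 age_restricted = isTRUE(age_restricted),
                 hl_groups = as.integer(hl_groups), ci_level = ci_level,
                 outcomes_used = outcomes_used,
                 write_bundle = isTRUE(write_bundle),
                 verbose = isTRUE(verbose)), class = "run_config")
}

stage <- function(verbose, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  if (verbose)
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full benchmark pipeline
#'
#' Generates a claims bundle, builds the configured cohorts (plus their 65+
#' restrictions), computes comorbidity profiles and outcomes, evaluates the
#' five measures per cohort and outcome, and writes the report tables:
#' cohort descriptives, Elixhauser condition prevalence, one performance
#' table per cohort variant, and a run manifest with config hash and file
#' checksums.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return (invisibly) a list with all tables and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- stage(v, "generate", generate_claims_bundle(config$generator))
  if (config$write_bundle)
    stage(v, "write-bundle", write_bundle(bundle, file.path(out_dir, "bundle")))

  variants <- list()   # label -> list(cohort, profiles, outcomes)
  for (lab in config$cohort_labels) {
    coh <- stage(v, paste0("cohort-", lab), build_cohort(bundle, cohort_spec(lab)))
    prof <- stage(v, paste0("profiles-", lab),
                  build_profiles(bundle, coh))
    oc <- stage(v, paste0("outcomes-", lab), derive_outcomes(bundle, coh))
    variants[[lab]] <- list(cohort = coh, profiles = prof, outcomes = oc)
    if (config$age_restricted) {
      coh65 <- restrict_age(coh, 65L)
      ids <- coh65$members$person_id
      variants[[paste0(lab, "_65plus")]] <- list(
        cohort = coh65,
        profiles = prof[person_id %in% ids],
        outcomes = oc[person_id %in% ids])
    }
  }

  descriptives <- stage(v, "descriptives", cohort_descriptives(variants))
  elix_prev <- stage(v, "elixhauser-prevalence",
                     elixhauser_prevalence(variants))
  performance <- list()
  for (nm in names(variants)) {
    vr <- variants[[nm]]
    performance[[nm]] <- stage(v, paste0("evaluate-", nm),
      evaluate_measures(vr$cohort, vr$profiles, vr$outcomes,
                        outcomes_used = config$outcomes_used,
                        hl_groups = config$hl_groups,
                        ci_level = config$ci_level))
  }

  files <- character()
  wr <- function(x, name) {
    f <- file.path(out_dir, name)
    data.table::fwrite(x, f, dateTimeAs = "ISO")
    files <<- c(files, f)
    f
  }
  wr(descriptives, "descriptives.csv")
  wr(elix_prev, "elixhauser_prevalence.csv")
  for (nm in names(performance)) {
    wr(performance[[nm]], sprintf("performance_%s.csv", nm))
    wr(render_performance_table(performance[[nm]]),
       sprintf("performance_%s_formatted.csv", nm))
  }

  manifest <- list(
    package = "comorbibench",
    version = as.character(utils::packageVersion("comorbibench")),
    seed = config$generator$seed,
    n_persons = config$generator$n_persons,
    config_hash = hash_config(config),
    tables = lapply(stats::setNames(files, basename(files)),
                    function(f) unname(tools::md5sum(f))))
  manifest_file <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(bundle = bundle, variants = variants,
                 descriptives = descriptives,
                 elixhauser_prevalence = elix_prev,
                 performance = performance, manifest = manifest,
                 files = c(files, manifest_file)))
}

## Stable hash of a run configuration (dates and vectors flattened to JSON).
hash_config <- function(config) {
  strip <- function(x) {
    if (inherits(x, "Date")) return(as.character(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    if (is.atomic(x) && !is.null(names(x))) return(lapply(as.list(x), strip))
    x
  }
  js <- jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}

## Table-1-shaped summary: one row per cohort variant.
cohort_descriptives <- function(variants) {
  data.table::rbindlist(lapply(names(variants), function(nm) {
    vr <- variants[[nm]]
    m <- vr$cohort$members; oc <- vr$outcomes; pr <- vr$profiles
    qd <- function(q) 100 * mean(!is.na(m$income_quintile) & m$income_quintile == q)
    data.table::data.table(
      cohort = nm, n = nrow(m),
      age_mean = mean(m$age_at_reference), age_sd = stats::sd(m$age_at_reference),
      female_pct = 100 * mean(m$sex == "F"),
      urban_pct = 100 * mean(m$region == "urban"),
      region_missing_pct = 100 * mean(m$region == "missing"),
      q1_pct = qd(1), q2_pct = qd(2), q3_pct = qd(3), q4_pct = qd(4),
      q5_pct = qd(5),
      q_missing_pct = 100 * mean(is.na(m$income_quintile)),
      death_pct = 100 * mean(oc$death),
      hosp_ge1_pct = 100 * mean(oc$hosp_ge1),
      hosp_ge2_pct = 100 * mean(oc$hosp_ge2),
      n_diagnoses_mean = mean(pr$n_diagnoses), n_diagnoses_sd = stats::sd(pr$n_diagnoses),
      charlson_mean = mean(pr$charlson), charlson_sd = stats::sd(pr$charlson),
      n_drugs_mean = mean(pr$n_drugs), n_drugs_sd = stats::sd(pr$n_drugs),
      cds_mean = mean(pr$cds), cds_sd = stats::sd(pr$cds))
  }))
}

## Table-2-shaped summary: Elixhauser condition prevalence (%) per variant.
elixhauser_prevalence <- function(variants) {
  conds <- elixhauser_conditions()
  cols <- sprintf("elix_%02d", 1:31)
  out <- data.table::data.table(condition = conds)
  for (nm in names(variants)) {
    pr <- variants[[nm]]$profiles
    out[[nm]] <- if (nrow(pr)) 100 * colMeans(as.matrix(pr[, ..cols])) else
      rep(NA_real_, 31)
  }
  out
}

#' Render a performance table in the printed layout
#'
#' Columns: model, c-statistic with 95% CI, Brier score with SD, and the
#' change in c with percent change, all to three decimals; base-model rows
#' show "--" for the change columns.
#'
#' @param results a performance table from [evaluate_measures()].
#' @return `data.table` with character columns outcome, model, `c_ci`,
#'   `brier_sd`, `delta_c_pct`.
#' @export
render_performance_table <- function(results) {
  if (!nrow(results))
    return(data.table::data.table(outcome = character(), model = character(),
                                  c_ci = character(), brier_sd = character(),
                                  delta_c_pct = character()))
  f3 <- function(x) formatC(x, digits = 3, format = "f")
  results[, .(
    outcome, model,
    c_ci = sprintf("%s (%s, %s)", f3(c), f3(ci_low), f3(ci_high)),
    brier_sd = sprintf("%s (%s)", f3(brier), f3(brier_sd)),
    delta_c_pct = data.table::fifelse(
      model == "base", "--",
      sprintf("%s (%s)", f3(delta_c), formatC(pct_change_c, digits = 2,
                                              format = "f"))))]
}
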