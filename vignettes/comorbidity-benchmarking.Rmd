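---
title: "Benchmarking claims-based comorbidity measures: models, design choices, and what the synthetic data can show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking claims-based comorbidity measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbibench)
library(data.table)
```

## The problem

Observational studies built on administrative health data must adjust for
pre-existing illness, and several summary measures compete for that role:
a simple count of distinct diagnoses, the Charlson index (17 weighted
conditions), the Elixhauser set (31 unweighted condition indicators), a
count of distinct dispensed drug classes, and the pharmacy-based Chronic
Disease Score (CDS). `comorbibench` implements a complete, testable
pipeline for comparing these measures as predictors of one-year death and
hospitalization across population-based cohorts: a general adult cohort
and two chronic-disease cohorts (diabetes, osteoporosis) defined by
claims-based case definitions.

Because real provincial registry data cannot be redistributed, the package
pairs the analysis pipeline with a synthetic claims generator whose
outcome-generating models are known. Every stage — cohort construction,
condition coding, model fitting, discrimination and calibration statistics
— can therefore be validated against ground truth or against independent
brute-force oracles.

## Data model

A `claims_bundle` holds five linked tables keyed by an opaque person
identifier, emulating a provincial system:

* **registry** — demographics (birth date, sex, urban/rural region, income
  quintile with an explicit missing category) and death date;
* **coverage** — non-overlapping health-insurance coverage intervals;
* **hospital** — discharge abstracts, one row per recorded diagnosis, with
  the coding system (ICD-9 or ICD-10), and a diagnosis type distinguishing
  the most responsible diagnosis, comorbid diagnoses, and post-admission
  complications;
* **physician** — fee-for-service claims carrying a single 3-digit ICD-9
  code;
* **drugs** — outpatient dispensations with AHFS pharmacologic-therapeutic
  class codes and an optional ingredient label.

All windows follow the April 1 – March 31 fiscal year: case finding over
1996/97–2001/02, comorbidity assessment in 2001/02, outcomes in 2002/03.

## Cohort definitions

* **General**: all registered persons aged 20+ (completed years at
  2002-04-01), alive on that date, with uninterrupted coverage over the
  comorbidity and outcome years.
* **Diabetes**: one hospital diagnosis (ICD-9 250, ICD-10 E10–E14) or two
  physician claims within a two-year window during case finding; the index
  date is the earliest qualifying diagnosis.
* **Osteoporosis** (age 50+): one hospital or physician diagnosis (ICD-9
  733, ICD-10 M80/M81) or one dispensation of an osteoprotective drug;
  persons with any Paget's disease code (731.0, M88.0/.8/.9) are excluded.

Design choices where the published definitions leave room:

* **Coverage and death.** "Uninterrupted coverage" is satisfied up to the
  death date for persons dying inside the coverage period. Without this
  reading, decedents — whose death is the primary outcome — could never be
  cohort members.
* **Two-year claim rule.** The two physician claims must fall within 730
  days of each other (a sliding window over claim dates), the most literal
  reading of "within a two-year period".
* **Code matching.** Codes are normalized (periods stripped, uppercased)
  and matched by prefix, or by range on the leading characters for rubric
  ranges such as E10–E14. No ICD-9↔ICD-10 cross-walk is attempted.
* **Age.** Completed years at a single reference date (2002-04-01), which
  makes the 65+ restriction deterministic.
* **Osteoprotective drugs** are recognized by ingredient label when
  present, with a bundled AHFS-class fallback.

## The five measures

All measures use one year of claims (fiscal 2001/02). Diagnoses coded to
pregnancy, childbirth, or abortion are excluded throughout, since those
contacts are not disease-related.

1. **Distinct diagnoses** — the number of distinct (coding system,
   first-three-character) pairs across hospital and physician data. The
   published exclusion of post-admission complication diagnoses is stated
   for the index calculations, so the count retains them (configurable via
   the filtering policy).
2. **Charlson index** — 17 conditions from the Quan coding algorithm with
   weights 1–6 and three hierarchy rules (complicated diabetes over
   uncomplicated, moderate/severe liver disease over mild, metastatic
   tumor over non-metastatic malignancy). With the bundled weights the
   attainable maximum after hierarchy resolution is 29; sources sometimes
   print "0 to 32", which no subset of the Quan weights reproduces
   exactly, so the package documents its own attainable maximum rather
   than forcing a printed bound.
3. **Elixhauser indicators** — 31 conditions, each entered into models as
   its own dichotomous variable; no summary weighting. The indicator order
   is fixed and documented (`elixhauser_conditions()`).
4. **Distinct drug classes** — distinct two-level ("four-digit") AHFS
   class prefixes, capped at 125.
5. **CDS** — 17 drug-treated conditions scored 1–5 and summed, some tiered
   by the number of distinct matched classes (heart disease scores 3/4/5
   for 1/2/3+ classes; a diuretic-only profile earns the reduced
   hypertension score). The original tier rules are not fully recoverable
   from the published constants (17 conditions, scores 1–5, total 0–35),
   so the bundled table is a reconstruction of the published scoring
   constrained so that the per-condition maxima sum to exactly 35; the
   table ships as editable CSV and its constants are validated at load
   time.

A practical consequence of 3-digit physician coding: conditions whose
shortest ICD-9 pattern exceeds three characters (complicated diabetes,
Paget's disease, several others) are only detectable from hospital data.
This information loss is real, not an artifact; the generator routes such
conditions through the hospital channel.

## Outcomes

Death is read from the registry death date inside the outcome year.
Hospitalizations are counted by admission date; a stay is
pregnancy-related — and excluded — when its *most responsible* diagnosis
is in the exclusion set; secondary pregnancy codes do not exclude a stay.
Thresholded indicators (at least one, two or more) derive from the count,
so their coherence (`ge2` implies `ge1`) is structural.

## Evaluation

For each cohort and outcome, a base logistic model (age, age², sex,
region, income quintile — missing region/quintile as explicit categories)
is compared with five full models, each adding one measure (the Elixhauser
set as 31 indicators, the others as single continuous terms). Fitting is
maximum likelihood via IRLS (`stats::glm.fit`), tolerance 1e-8, at most
100 iterations; collinear and zero-variance columns are pruned with a
warning, perfect separation (zero residual deviance) is an error naming
the offending column, and covariance comes from a QR factorization of the
weighted design, which keeps the age² column from squaring the condition
number.

Reported per model:

* **c-statistic**: computed by midranks, equal to brute-force case–control
  pair counting with ties counted half.
* **DeLong confidence interval and paired test**: placement values with
  midrank tie handling give the variance of one AUC and the covariance of
  two correlated AUCs on the same persons. Identical score vectors return
  p = 1 rather than 0/0. The same machinery gives Δc and its p-value
  against the base model; the interval method for single c-statistics is
  a package choice, since published reports rarely name one.
* **Brier score** with an SD read as the sample standard deviation of the
  per-person squared errors — the only per-person quantity available;
  note this is a dispersion of squared errors, not a standard error of
  the mean score.
* **Hosmer-Lemeshow**: deciles of predicted risk with stable ordering and
  tied predictions kept together in the lower group;
  χ² = Σ (O−E)²/(E(1−E/n_g)), df = groups − 2.
* **McNemar** (for overlapping cohorts): uncorrected χ² on discordant
  pairs with an exact binomial fallback when b + c < 25, and an explicit
  no-discordance status when b + c = 0.

Outcomes with fewer than 10 events are flagged unstable but still
computed; outcomes that are constant, or models that cannot be estimated
in a tiny cohort, yield NA rows rather than aborting a pipeline run.

## The synthetic generator

`generator_config()` defaults define the study conditions:

* **Demographics**: ages from a shifted gamma (mean ≈ 48, SD ≈ 18 among
  adults), 51.3% female, 58.2% urban, 1.2% missing income quintile.
* **Latent conditions**: the 31 Elixhauser categories at general-adult
  prevalences (16.7% uncomplicated hypertension down to 0.05% HIV), plus
  osteoporosis (4%) and Paget's disease (0.1%) for the cohort
  definitions. Conditions are drawn independently across categories —
  real comorbidities cluster, and this simplification is the main respect
  in which the synthetic data are easier than real data.
* **Coding**: every latent condition emits at least one mapped code in
  the assessment year (physician channel with probability 0.7 when a
  3-digit code can express it, hospital otherwise); cohort-qualifying
  codes appear in the six-year case window with probability 0.95. Acute
  "noise" diagnoses (injury rubrics disjoint from every condition map)
  follow a negative binomial with age-increasing mean, so the distinct
  diagnosis count has realistic dispersion (mean ≈ 3.5, SD ≈ 3.9).
  Pregnancy-coded contacts and post-admission complication diagnoses are
  layered in to exercise the exclusion rules.
* **Drugs**: background dispensing at 1.3 distinct classes per
  person-year plus condition-linked classes (hypertensives for latent
  hypertension, antidiabetics for diabetes, and so on) with probability
  0.7, so the drug-based measures correlate with true illness burden.
* **Outcomes**: death is Bernoulli on a logit-linear predictor with
  strong age effects and heterogeneous condition effects (metastatic
  cancer +2.5 log-odds, heart failure +1.3, uncomplicated hypertension
  +0.1); hospitalization counts are Poisson on a log-linear predictor in
  total diagnosis burden, so one generating process induces both
  threshold outcomes. Intercepts were calibrated once, by simulation
  against the published general-population rates (death 1.3%, ≥1
  hospitalization 17.4%, ≥2 hospitalizations 5.1%), and are not tuned
  thereafter.

This design makes the qualitative benchmark outcome a *property of the
generating process*: death depends on *which* conditions a person has, so
the indicator-per-condition model (Elixhauser) can exploit information
that any scalar summary discards, while hospitalization depends on *how
much* total diagnosis burden a person carries, which the distinct
diagnosis count measures most directly. Passing the ranking-recovery test
therefore shows that the pipeline correctly identifies measures matched
to outcome structure — it does not show that real provincial claims data
have that structure, and it cannot validate the condition maps against
real coding practice.

## Test design and problem sizes

The suite validates at three levels, with sizes chosen to keep the whole
run within a coffee break on one CPU:

* exact oracles: brute-force pair enumeration for the c-statistic (100
  random instances, n ≤ 200), an independent per-person scorer for all
  five measures (200-person bundles), and per-person re-checks of cohort
  predicates and outcome derivation;
* statistical validity: DeLong paired-test size and CI coverage under the
  null (2,000 replicates at n = 200), and logistic parameter recovery
  within 3 standard errors at n = 50,000;
* system level: ranking recovery over 20 generator replicates at
  n = 50,000 (required in at least 90%), and byte-identical report
  checksums for repeated runs at the same scale.

## Known limitations

* Conditions are independent in the generator; no age gradient in
  prevalence (age acts on outcomes directly).
* Physician claims are uniformly 3-digit ICD-9; shadow-billing
  completeness and coding drift are not modelled.
* The CDS tier table is a constrained reconstruction (see above), shipped
  as data so it can be replaced wholesale.
* Hospitalizations are independent records: no transfers, episodes of
  care, or same-day readmission linkage.
* Income quintiles are generated directly; no census-linkage or
  imputation machinery is modelled, and missingness is
  missing-completely-at-random.
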