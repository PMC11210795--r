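# Shared fixtures: hand-built micro-datasets, random small datasets for the
# attrition oracle, and a lazily built full-scale simulation shared by the
# acceptance tests.

make_dataset <- function(patients, visits = NULL, vitals = NULL, labs = NULL,
                         meds = NULL, procs = NULL) {
  empty_visits <- tibble::tibble(visit_id = character(),
                                 patient_id = character(),
                                 date = as.Date(character()),
                                 visit_type = character(),
                                 provider_specialty = character(),
                                 in_person = logical())
  empty_dated <- function(...) tibble::tibble(patient_id = character(),
                                              date = as.Date(character()), ...)
  dq_dataset(
    patients = patients,
    visits = visits %||% empty_visits,
    vitals = vitals %||% empty_dated(measure = character(),
                                     value = numeric(), unit = character()),
    labs = labs %||% empty_dated(lab = character(), value = numeric(),
                                 unit = character()),
    meds = meds %||% empty_dated(drug_class = character()),
    procs = procs %||% empty_dated(code = character(),
                                   code_group = character()))
}

one_patient <- function(pid = "p1", site = "s1", birth = "2005-03-05") {
  tibble::tibble(patient_id = pid, site_id = site,
                 birth_date = as.Date(birth), sex = "female", race = "white",
                 ethnicity = "non_hispanic", geocode_level = "block_group")
}

# the hand-traced cohort patient: eGFR 48.18 at CED, lows at +100 and +210
# days, nephrology in-person visit, no dialysis/transplant
trace_patient_dataset <- function(insert_normal = FALSE) {
  d0 <- as.Date("2015-03-10")
  scr_for <- function(egfr) 0.413 * 140 / egfr
  labs <- tibble::tibble(
    patient_id = "p1",
    date = c(d0, d0 + 100, d0 + 210),
    lab = "serum_creatinine",
    value = c(1.2, scr_for(45), scr_for(44)),
    unit = "mg/dL")
  if (insert_normal)
    labs <- dplyr::bind_rows(labs, tibble::tibble(
      patient_id = "p1", date = d0 + 50, lab = "serum_creatinine",
      value = scr_for(95), unit = "mg/dL"))
  vitals <- tibble::tibble(
    patient_id = "p1",
    date = c(d0 - 10, d0 + 100, d0 + 210, if (insert_normal) d0 + 50),
    measure = "height", value = 140, unit = "cm")
  visits <- tibble::tibble(
    visit_id = c("v1", "v2"), patient_id = "p1",
    date = c(as.Date("2015-03-01"), d0 + 30),
    visit_type = "outpatient",
    provider_specialty = c("general_pediatrics", "nephrology"),
    in_person = TRUE)
  make_dataset(one_patient(), visits = visits, vitals = vitals, labs = labs)
}

# randomized small dataset exercising all attrition steps and edge cases
random_small_dataset <- function(seed) {
  set.seed(seed)
  n <- sample(5:50, 1)
  sites <- sample(c("sA", "sB"), n, replace = TRUE)
  pid <- sprintf("p%03d", seq_len(n))
  birth <- as.Date("2000-01-01") + sample.int(15 * 365, n, replace = TRUE)
  patients <- tibble::tibble(patient_id = pid, site_id = sites,
                             birth_date = birth, sex = "female",
                             race = "white", ethnicity = "non_hispanic",
                             geocode_level = "zip5")
  rnd_dates <- function(k, lo = "2008-06-01", hi = "2022-06-01")
    as.Date(lo) + sample.int(as.integer(as.Date(hi) - as.Date(lo)), k,
                             replace = TRUE)
  nv <- sample(0:8, n, replace = TRUE)
  vi <- rep(seq_len(n), nv)
  vtype <- sample(c("outpatient", "inpatient", "telehealth",
                    "administrative"), length(vi), replace = TRUE)
  visits <- tibble::tibble(
    visit_id = sprintf("v%04d", seq_along(vi)), patient_id = pid[vi],
    date = rnd_dates(length(vi)), visit_type = vtype,
    provider_specialty = sample(c("nephrology", "general_pediatrics", "none"),
                                length(vi), replace = TRUE, prob = c(.3, .4, .3)),
    in_person = !(vtype %in% c("telehealth", "administrative")))
  nl <- sample(0:10, n, replace = TRUE)
  li <- rep(seq_len(n), nl)
  labs <- tibble::tibble(
    patient_id = pid[li], date = rnd_dates(length(li)),
    lab = "serum_creatinine",
    value = round(stats::runif(length(li), -0.1, 3), 3), # a few implausible
    unit = "mg/dL")
  nh <- sample(0:6, n, replace = TRUE)
  hi_ <- rep(seq_len(n), nh)
  vitals <- tibble::tibble(
    patient_id = pid[hi_], date = rnd_dates(length(hi_)), measure = "height",
    value = round(stats::runif(length(hi_), 70, 180), 1), unit = "cm")
  np <- stats::rbinom(n, 2, 0.15)
  pi_ <- rep(seq_len(n), np)
  procs <- tibble::tibble(
    patient_id = pid[pi_], date = rnd_dates(length(pi_)),
    code = "90935",
    code_group = sample(c("chronic_dialysis", "kidney_transplant", "other"),
                        length(pi_), replace = TRUE))
  make_dataset(patients, visits = visits, vitals = vitals, labs = labs,
               procs = procs)
}

# shared full-scale simulation (built at most once per test run)
.sim_cache <- new.env(parent = emptyenv())

default_sim_clean <- function() {
  if (is.null(.sim_cache$clean))
    .sim_cache$clean <- generate_network(sim_config(seed = 20090913 %% 1000))
  .sim_cache$clean
}

default_sim_planted <- function() {
  if (is.null(.sim_cache$planted)) {
    ds <- default_sim_clean()
    .sim_cache$planted <- inject_anomalies(ds, default_plants(ds), seed = 101)
  }
  .sim_cache$planted
}

`%||%` <- function(a, b) if (is.null(a)) b else a
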