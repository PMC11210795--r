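# Multi-site synthetic EHR generator: CKD trajectories with known-truth eGFR,
# correlated blood pressures, specialty utilization, dialysis/transplant
# codes and geocode granularity.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is calibrated to:
#' 15 heterogeneous pediatric sites observed over 2009-2021, with roughly a
#' third of patients carrying a progressive CKD trajectory.
#'
#' @param n_sites Number of sites.
#' @param patients_per_site Patients per site.
#' @param study_interval `c(start_year, end_year)`.
#' @param ckd_fraction Probability a patient carries a CKD trajectory.
#' @param baseline_egfr_range eGFR (mL/min/1.73m2) at the trajectory anchor.
#' @param egfr_decline_mean,egfr_decline_sd eGFR decline, mL/min/1.73m2 per
#'   year (negative mean).
#' @param bp_correlation Target Pearson correlation of same-day systolic and
#'   diastolic blood pressure.
#' @param visit_rate Mean visits per patient-year (all specialties).
#' @param neph_visit_rate Mean nephrology visits per patient-year for CKD
#'   patients.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 15,
                       patients_per_site = 1000,
                       study_interval = c(2009L, 2021L),
                       ckd_fraction = 0.3,
                       baseline_egfr_range = c(30, 90),
                       egfr_decline_mean = -3,
                       egfr_decline_sd = 0.5,
                       bp_correlation = 0.6,
                       visit_rate = 3,
                       neph_visit_rate = 2,
                       seed = 42L) {
  stopifnot(n_sites >= 1, patients_per_site >= 1,
            ckd_fraction >= 0, ckd_fraction <= 1,
            bp_correlation > -1, bp_correlation < 1,
            baseline_egfr_range[1] < baseline_egfr_range[2],
            visit_rate > 0)
  structure(list(n_sites = as.integer(n_sites),
                 patients_per_site = as.integer(patients_per_site),
                 study_interval = as.integer(study_interval),
                 ckd_fraction = ckd_fraction,
                 baseline_egfr_range = baseline_egfr_range,
                 egfr_decline_mean = egfr_decline_mean,
                 egfr_decline_sd = egfr_decline_sd,
                 bp_correlation = bp_correlation,
                 visit_rate = visit_rate,
                 neph_visit_rate = neph_visit_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Median growth curve: piecewise linear, 75 cm at age 1 -> 140 cm at age 12
# -> 170 cm at age 18; flat outside. Only ordinal plausibility matters.
growth_median <- function(age) {
  a <- pmin(pmax(age, 1), 18)
  ifelse(a <= 12, 75 + (140 - 75) * (a - 1) / 11, 140 + (170 - 140) * (a - 12) / 6)
}

rcat <- function(n, codes, prob) codes[sample.int(length(codes), n, replace = TRUE, prob = prob)]

#' Generate a multi-site synthetic EHR network
#'
#' Deterministic given the config seed. Each CKD patient carries a linear
#' eGFR trajectory; serum creatinine is back-computed from the bedside
#' Schwartz relation given the patient's simulated height, and a height vital
#' is recorded on every creatinine date, so the eGFR implied by the stored
#' records is known exactly. Systolic/diastolic pairs are drawn from a
#' bivariate normal with the configured correlation (means 105/65 mmHg, SDs
#' 12/9). The truth table of record-implied eGFRs is attached as attribute
#' `egfr_truth` (not persisted by [write_dataset()]).
#'
#' @param config A [sim_config()].
#' @return A `dq_dataset`.
#' @export
generate_network <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  k <- 0.413
  int <- config$study_interval
  t0 <- as.Date(sprintf("%d-01-01", int[1]))
  t1 <- as.Date(sprintf("%d-12-31", int[2]))

  n_sites <- config$n_sites
  npat <- config$patients_per_site
  n <- n_sites * npat
  site_id <- rep(sprintf("site%02d", seq_len(n_sites)), each = npat)
  patient_id <- sprintf("%s-p%04d", site_id, rep(seq_len(npat), n_sites))

  birth_lo <- as.Date(sprintf("%d-01-01", int[1] - 9))
  birth_hi <- as.Date(sprintf("%d-12-31", int[2] - 7))
  birth_date <- birth_lo + round(stats::runif(n, 0, as.numeric(birth_hi - birth_lo)))

  patients <- tibble::tibble(
    patient_id = patient_id, site_id = site_id, birth_date = birth_date,
    sex = rcat(n, c("male", "female"), c(.5, .5)),
    race = rcat(n, c("white", "black", "asian", "other", "missing"),
                c(.55, .2, .08, .12, .05)),
    ethnicity = rcat(n, c("hispanic", "non_hispanic", "missing"),
                     c(.2, .75, .05)),
    geocode_level = rcat(n, c("block_group", "tract", "zip9", "zip5", "none"),
                         c(.6, .2, .1, .07, .03)))

  ckd <- stats::runif(n) < config$ckd_fraction
  baseline <- stats::runif(n, config$baseline_egfr_range[1],
                           config$baseline_egfr_range[2])
  decline <- stats::rnorm(n, config$egfr_decline_mean, config$egfr_decline_sd)
  anchor_age <- stats::runif(n, 3, 10)
  anchor_date <- birth_date + round(anchor_age * 365.25)
  height_offset <- pmin(pmax(stats::rnorm(n, 0, 5), -10), 10)
  egfr_normal_base <- stats::runif(n, 100, 130)

  # record-level eGFR target at a date, per patient index
  egfr_at <- function(i, dates) {
    ifelse(ckd[i],
           pmax(5, baseline[i] + decline[i] *
                  as.numeric(dates - anchor_date[i]) / 365.25),
           egfr_normal_base[i] + stats::rnorm(length(i), 0, 5))
  }
  height_at <- function(i, dates) {
    growth_median(age_years(dates, birth_date[i])) + height_offset[i]
  }

  # active observation window: ages [1, 19] intersected with the interval
  act_lo <- pmax(birth_date + 365, t0)
  act_hi <- pmin(birth_date + round(19 * 365.25), t1)
  act_years <- pmax(as.numeric(act_hi - act_lo), 0) / 365.25

  draw_dates <- function(i, nrec) {
    # nrec records for patient index i, uniform over the active window
    idx <- rep(i, nrec)
    d <- act_lo[idx] + round(stats::runif(sum(nrec)) *
                               as.numeric(act_hi[idx] - act_lo[idx]))
    list(idx = idx, date = d)
  }

  ## visits ------------------------------------------------------------
  n_gen <- stats::rpois(n, config$visit_rate * act_years)
  gv <- draw_dates(seq_len(n), n_gen)
  vtype <- rcat(length(gv$idx),
                c("outpatient", "other_ambulatory", "inpatient",
                  "telehealth", "administrative"),
                c(.60, .15, .08, .07, .10))
  spec <- rcat(length(gv$idx), c("general_pediatrics", "cardiology", "none"),
               c(.5, .1, .4))
  gen_visits <- tibble::tibble(patient_id = patient_id[gv$idx],
                               date = gv$date, visit_type = vtype,
                               provider_specialty = spec)

  ckd_idx <- which(ckd)
  n_neph <- stats::rpois(length(ckd_idx),
                         config$neph_visit_rate * act_years[ckd_idx])
  nv <- draw_dates(ckd_idx, n_neph)
  neph_visits <- tibble::tibble(patient_id = patient_id[nv$idx],
                                date = nv$date, visit_type = "outpatient",
                                provider_specialty = "nephrology")
  visits <- dplyr::bind_rows(gen_visits, neph_visits)
  visits$in_person <- !(visits$visit_type %in% c("telehealth", "administrative"))
  visits <- visits[!is.na(visits$date) & visits$date >= t0 & visits$date <= t1, ]
  visits$visit_id <- sprintf("v%07d", seq_len(nrow(visits)))
  visits <- visits[, c("visit_id", "patient_id", "date", "visit_type",
                       "provider_specialty", "in_person")]
  visit_idx <- match(visits$patient_id, patient_id)

  ## labs ----------------------------------------------------------------
  neph_v <- visits[visits$provider_specialty == "nephrology", ]
  neph_i <- match(neph_v$patient_id, patient_id)

  scr_rows <- function(idx, dates) {
    e <- egfr_at(idx, dates)
    h <- height_at(idx, dates)
    tibble::tibble(patient_id = patient_id[idx], date = dates,
                   lab = "serum_creatinine", value = k * h / e,
                   unit = "mg/dL", height = h)
  }
  keep <- stats::runif(nrow(neph_v)) < 0.9
  scr_ckd <- scr_rows(neph_i[keep], neph_v$date[keep])

  gp_v <- visits[visits$provider_specialty == "general_pediatrics" &
                   visits$in_person, ]
  gp_i <- match(gp_v$patient_id, patient_id)
  keep <- !ckd[gp_i] & stats::runif(nrow(gp_v)) < 0.25
  scr_gen <- scr_rows(gp_i[keep], gp_v$date[keep])
  scr <- dplyr::bind_rows(scr_ckd, scr_gen)

  cys_adopter <- stats::runif(n) < 0.3
  keep <- cys_adopter[neph_i] & stats::runif(nrow(neph_v)) < 0.3 &
    year_of(neph_v$date) >= 2016
  cys <- tibble::tibble(patient_id = neph_v$patient_id[keep],
                        date = neph_v$date[keep], lab = "serum_cystatin_c",
                        value = stats::runif(sum(keep), 0.6, 2.5),
                        unit = "mg/L")

  keep <- stats::runif(nrow(neph_v)) < 0.5
  upr <- tibble::tibble(patient_id = neph_v$patient_id[keep],
                        date = neph_v$date[keep], lab = "urine_protein_quant",
                        value = pmin(stats::rlnorm(sum(keep), log(40), 1), 4000),
                        unit = "mg/dL")
  keep <- stats::runif(nrow(neph_v)) < 0.3
  ucr <- tibble::tibble(patient_id = neph_v$patient_id[keep],
                        date = neph_v$date[keep], lab = "urine_creatinine",
                        value = stats::runif(sum(keep), 20, 300),
                        unit = "mg/dL")
  labs <- dplyr::bind_rows(scr[, c("patient_id", "date", "lab", "value", "unit")],
                           cys, upr, ucr)

  ## vitals --------------------------------------------------------------
  ip <- visits$in_person
  bp_take <- ip & stats::runif(nrow(visits)) < 0.7
  z1 <- stats::rnorm(sum(bp_take)); z2 <- stats::rnorm(sum(bp_take))
  r <- config$bp_correlation
  sys <- 105 + 12 * z1
  dia <- 65 + 9 * (r * z1 + sqrt(1 - r^2) * z2)
  bp <- tibble::tibble(
    patient_id = rep(visits$patient_id[bp_take], 2),
    date = rep(visits$date[bp_take], 2),
    measure = rep(c("systolic_bp", "diastolic_bp"), each = sum(bp_take)),
    value = c(sys, dia), unit = "mmHg")

  ht_take <- ip & stats::runif(nrow(visits)) < 0.5
  ht_visit <- tibble::tibble(patient_id = visits$patient_id[ht_take],
                             date = visits$date[ht_take],
                             value = height_at(visit_idx[ht_take],
                                               visits$date[ht_take]))
  ht_scr <- tibble::tibble(patient_id = scr$patient_id, date = scr$date,
                           value = scr$height)
  heights <- dplyr::bind_rows(ht_visit, ht_scr) |>
    dplyr::distinct(.data$patient_id, .data$date, .keep_all = TRUE) |>
    dplyr::mutate(measure = "height", unit = "cm")

  wt_take <- ip & stats::runif(nrow(visits)) < 0.5
  wt_age <- age_years(visits$date[wt_take], birth_date[visit_idx[wt_take]])
  weights <- tibble::tibble(
    patient_id = visits$patient_id[wt_take], date = visits$date[wt_take],
    measure = "weight", unit = "kg",
    value = pmax(6, 9 + 3.3 * (wt_age - 1) + stats::rnorm(sum(wt_take), 0, 2)))
  vitals <- dplyr::bind_rows(bp, heights[, c("patient_id", "date", "measure",
                                             "value", "unit")], weights)

  ## medications ----------------------------------------------------------
  # first antihypertensive relative to the approximate onset of low eGFR
  t90 <- anchor_date + round((90 - baseline) / decline * 365.25)
  onset <- pmax(t90 + 90, act_lo)
  on_med <- ckd & stats::runif(n) < 0.8
  med_i <- which(on_med)
  first_med <- onset[med_i] + round(stats::runif(length(med_i), -200, 800))
  dur_days <- round(stats::runif(length(med_i), 0.5, 3) * 365.25)
  n_fills <- pmax(1L, as.integer(dur_days / 60))
  fill_idx <- rep(seq_along(med_i), n_fills)
  fill_no <- sequence(n_fills)
  first_class <- rcat(length(med_i),
                      c("acei_arb", "calcium_channel_blocker", "loop_diuretic",
                        "thiazide", "beta_blocker"), c(.5, .2, .1, .1, .1))
  meds_ah <- tibble::tibble(
    patient_id = patient_id[med_i][fill_idx],
    date = first_med[fill_idx] + (fill_no - 1) * 60,
    drug_class = first_class[fill_idx])
  oth_i <- which(stats::runif(n) < 0.05)
  go <- draw_dates(oth_i, stats::rpois(length(oth_i), 2))
  meds_other <- tibble::tibble(patient_id = patient_id[go$idx],
                               date = go$date, drug_class = "other")
  meds <- dplyr::bind_rows(meds_ah, meds_other)
  meds <- meds[meds$date >= t0 & meds$date <= t1, ]

  ## procedures -----------------------------------------------------------
  final_egfr <- ifelse(ckd, pmax(5, baseline + decline *
                                   as.numeric(act_hi - anchor_date) / 365.25),
                       egfr_normal_base)
  dial_i <- which(ckd & final_egfr < 30 & stats::runif(n) < 0.6)
  # dialysis starts when the trajectory crosses 25
  t25 <- anchor_date + round((25 - baseline) / decline * 365.25)
  dial_start <- pmax(t25[dial_i], act_lo[dial_i])
  n_mo <- pmax(1L, as.integer(as.numeric(act_hi[dial_i] - dial_start) / 30))
  d_idx <- rep(seq_along(dial_i), n_mo)
  d_no <- sequence(n_mo)
  procs_dial <- tibble::tibble(
    patient_id = patient_id[dial_i][d_idx],
    date = dial_start[d_idx] + (d_no - 1) * 30,
    code = rcat(length(d_idx), c("90935", "90937", "90945"), c(.4, .3, .3)),
    code_group = "chronic_dialysis")
  tx_i <- dial_i[stats::runif(length(dial_i)) < 0.15]
  procs_tx <- tibble::tibble(
    patient_id = patient_id[tx_i],
    date = act_hi[tx_i] - round(stats::runif(length(tx_i), 0, 180)),
    code = rcat(length(tx_i), c("50360", "50365"), c(.6, .4)),
    code_group = "kidney_transplant")
  oth_take <- stats::runif(nrow(visits)) < 0.10
  procs_oth <- tibble::tibble(
    patient_id = visits$patient_id[oth_take], date = visits$date[oth_take],
    code = rcat(sum(oth_take), c("99213", "99214", "36415", "71045"),
                c(.4, .3, .2, .1)),
    code_group = "other")
  procs <- dplyr::bind_rows(procs_dial, procs_tx, procs_oth)
  procs <- procs[procs$date >= t0 & procs$date <= t1, ]

  ds <- dq_dataset(patients, visits, vitals, labs, meds, procs)
  # truth: the eGFR implied by the stored creatinine/height records
  implied_egfr <- k * scr$height / scr$value
  truth <- tibble::tibble(patient_id = scr$patient_id, date = scr$date,
                          scr = scr$value, egfr_truth = implied_egfr)
  attr(ds, "egfr_truth") <- truth
  attr(ds, "sim_config") <- config
  ds
}
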