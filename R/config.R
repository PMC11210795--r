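# Value sets, schema configuration and analysis thresholds for the simplified
# six-domain common data model.

#' Value sets for coded fields of the common data model
#'
#' Returns the closed enumerations against which [validate_conformance()]
#' checks coded columns. Units are handled separately (see
#' `allowed_units` in [default_schema_config()]).
#'
#' @return Named list of character vectors.
#' @export
cdm_value_sets <- function() {
  list(
    ethnicity      = c("hispanic", "non_hispanic", "missing"),
    geocode_level  = c("none", "zip5", "zip9", "tract", "block_group"),
    sex            = c("male", "female", "other", "missing"),
    visit_type     = c("inpatient", "outpatient", "other_ambulatory",
                       "telehealth", "administrative"),
    measure        = c("systolic_bp", "diastolic_bp", "height", "weight"),
    vital_unit     = c("cm", "kg", "mmHg", "in", "lb", "missing"),
    lab            = c("serum_creatinine", "serum_cystatin_c",
                       "urine_protein_quant", "urine_creatinine"),
    drug_class     = c("acei_arb", "calcium_channel_blocker", "loop_diuretic",
                       "thiazide", "beta_blocker", "other"),
    code_group     = c("chronic_dialysis", "kidney_transplant", "other")
  )
}

#' Default schema configuration
#'
#' Describes the six domain files (required columns), the per-lab allowed-unit
#' lists that define `mapped_unit`, and physiologic bounds used by the
#' value-distribution checks. Units are stored verbatim; a unit maps when it is
#' non-missing and appears in the lab's allowed set.
#'
#' @return A list with elements `columns`, `allowed_units`, `bounds` and
#'   `value_sets`.
#' @export
default_schema_config <- function() {
  list(
    columns = list(
      patients = c("patient_id", "site_id", "birth_date", "sex", "race",
                   "ethnicity", "geocode_level"),
      visits   = c("visit_id", "patient_id", "date", "visit_type",
                   "provider_specialty", "in_person"),
      vitals   = c("patient_id", "date", "measure", "value", "unit"),
      labs     = c("patient_id", "date", "lab", "value", "unit"),
      meds     = c("patient_id", "date", "drug_class"),
      procs    = c("patient_id", "date", "code", "code_group")
    ),
    allowed_units = list(
      serum_creatinine    = "mg/dL",
      serum_cystatin_c    = "mg/L",
      urine_protein_quant = "mg/dL",
      urine_creatinine    = "mg/dL"
    ),
    # physiologic bounds (closed) for value-distribution checks; variables
    # without an entry are never flagged out-of-range
    bounds = list(
      "lab:urine_protein_quant" = c(0, 5000),
      "vital:height"            = c(60, 220)
    ),
    value_sets = cdm_value_sets()
  )
}

#' Analysis configuration: eligibility and detection thresholds
#'
#' All thresholds consumed by the eGFR/attrition pipeline and the anomaly
#' detectors live here, so a study can recalibrate without touching code.
#'
#' @param schwartz_k Bedside Schwartz constant (default 0.413).
#' @param egfr_low,egfr_high Qualifying eGFR interval, closed below and open
#'   above: `[egfr_low, egfr_high)` in mL/min/1.73m2.
#' @param height_window_days Maximum |days| between a serum creatinine and the
#'   height used to compute eGFR (closed window).
#' @param gap_days Minimum days between the first qualifying eGFR and each
#'   additional qualifying eGFR.
#' @param age_min,age_max Age window (years, closed) for eligible creatinines.
#' @param study_interval Integer vector `c(start_year, end_year)`.
#' @param spike_z Leave-one-out z-score threshold for yearly spike detection.
#' @param sd_floor_frac SD floor for spike detection, as a fraction of the
#'   leave-one-out mean.
#' @param fence_multiplier Tukey fence multiplier for cross-site outliers.
#' @param min_rel_dev Minimum relative deviation from the cross-site median
#'   for a fence breach to be reported (guards near-constant metrics).
#' @param min_sites Minimum number of sites for cross-site outlier detection.
#' @param prevalence_min Pooled prevalence below which codes are dropped from
#'   the code-utilization matrix.
#' @param mass_fraction_threshold Fraction of records sharing one exact value
#'   above which a distribution is flagged atypical.
#' @param correlation_floor Pearson r below which an expected-positive
#'   correlation is flagged discordant.
#' @param min_pairs Minimum concordant patient-days per site for the blood
#'   pressure correlation check.
#' @param expected_sparse Elements expected to be sparsely captured (assigned
#'   low priority when missing).
#'
#' @return A list of class `dq_config`.
#' @export
analysis_config <- function(schwartz_k = 0.413,
                            egfr_low = 30,
                            egfr_high = 90,
                            height_window_days = 90,
                            gap_days = 90,
                            age_min = 1,
                            age_max = 18,
                            study_interval = c(2009L, 2021L),
                            spike_z = 2.0,
                            sd_floor_frac = 0.05,
                            fence_multiplier = 1.5,
                            min_rel_dev = 0.2,
                            min_sites = 5,
                            prevalence_min = 0.005,
                            mass_fraction_threshold = 0.10,
                            correlation_floor = 0.2,
                            min_pairs = 3,
                            expected_sparse = c("serum_cystatin_c",
                                                "urine_creatinine",
                                                "chronic_dialysis",
                                                "kidney_transplant"),
                            schema = default_schema_config()) {
  stopifnot(egfr_low < egfr_high, egfr_low > 0, height_window_days > 0,
            gap_days > 0, age_min >= 0, age_min < age_max,
            spike_z > 0, fence_multiplier > 0, prevalence_min > 0,
            mass_fraction_threshold > 0, min_sites >= 2)
  structure(list(
    schwartz_k = schwartz_k, egfr_low = egfr_low, egfr_high = egfr_high,
    height_window_days = height_window_days, gap_days = gap_days,
    age_min = age_min, age_max = age_max,
    study_interval = as.integer(study_interval),
    spike_z = spike_z, sd_floor_frac = sd_floor_frac,
    fence_multiplier = fence_multiplier, min_rel_dev = min_rel_dev,
    min_sites = min_sites, prevalence_min = prevalence_min,
    mass_fraction_threshold = mass_fraction_threshold,
    correlation_floor = correlation_floor, min_pairs = min_pairs,
    expected_sparse = expected_sparse, schema = schema
  ), class = "dq_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys absent from the file keep their [analysis_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `dq_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  raw <- raw[intersect(names(raw), setdiff(known, "schema"))]
  do.call(analysis_config, raw)
}

#' @export
print.dq_config <- function(x, ...) {
  cat("<dq_config>\n")
  cat(sprintf("  eGFR window [%g, %g), Schwartz k = %g\n",
              x$egfr_low, x$egfr_high, x$schwartz_k))
  cat(sprintf("  height window +/-%d d, gap %d d, ages %g-%g y\n",
              x$height_window_days, x$gap_days, x$age_min, x$age_max))
  cat(sprintf("  study interval %d-%d\n",
              x$study_interval[1], x$study_interval[2]))
  cat(sprintf("  spike |z| > %g (SD floor %g of mean); fence %g*IQR, rel dev > %g\n",
              x$spike_z, x$sd_floor_frac, x$fence_multiplier, x$min_rel_dev))
  invisible(x)
}
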