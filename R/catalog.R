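# Encoded DQ1/DQ2 check catalogs. The supplementary catalogs of the source
# study are not public; these entries are synthesized to reproduce the
# published per-round, per-domain and per-category distributions, with
# summaries patterned on the published check-specification examples.
# Multi-category checks account for category tallies exceeding check counts
# (a single check's output can be post-processed for several categories).

CHECK_TYPES <- c("attribution", "attrition step check", "clinical correlation",
                 "clinical fact relationships", "clinical fact density",
                 "clinical thresholds", "code utilization",
                 "frequency distributions", "specialty correlation",
                 "summary statistics", "temporal relationships",
                 "trends over time", "utilization thresholds",
                 "variable stratifications")
CHECK_CATEGORIES <- c("completeness", "conformance", "plausibility",
                      "concordance", "consistency")
DQ_PROBES <- c("anomalous event sequencing", "anomalous values",
               "data representation error", "inconsistent trends")
CLINICAL_GOALS <- c("clinical care", "diagnostic evaluation",
                    "epidemiologic distribution", "utilization")
DQ_ISSUES <- c("atypical code distribution", "atypical numeric distribution",
               "discordant values", "high counts", "high spike", "low counts",
               "low spike", "mapping error", "missingness", "outlier values")
EXECUTORS <- c("completeness_trend", "same_day_concordance",
               "pair_correlation", "unit_mapped_proportion",
               "code_utilization", "med_timing", "geocode_granularity",
               "value_distribution", "attrition_funnel",
               "egfr_threshold_curve", "egfr_trajectory_medians",
               "yearly_count_trend", "per_patient_density",
               "category_frequency", "conformance_value_sets", "unbound")

executor_meta <- function(executor) {
  switch(executor,
    completeness_trend = c("trends over time", "data representation error",
                           "utilization"),
    same_day_concordance = c("clinical fact relationships",
                             "data representation error", "clinical care"),
    pair_correlation = c("clinical correlation", "inconsistent trends",
                         "clinical care"),
    unit_mapped_proportion = c("frequency distributions",
                               "data representation error", "clinical care"),
    code_utilization = c("code utilization", "anomalous values",
                         "utilization"),
    med_timing = c("temporal relationships", "anomalous event sequencing",
                   "clinical care"),
    geocode_granularity = c("frequency distributions",
                            "data representation error",
                            "epidemiologic distribution"),
    value_distribution = c("frequency distributions", "anomalous values",
                           "clinical care"),
    attrition_funnel = c("attrition step check", "anomalous values",
                         "epidemiologic distribution"),
    egfr_threshold_curve = c("clinical thresholds", "anomalous values",
                             "diagnostic evaluation"),
    egfr_trajectory_medians = c("trends over time",
                                "anomalous event sequencing", "clinical care"),
    yearly_count_trend = c("trends over time", "inconsistent trends",
                           "utilization"),
    per_patient_density = c("clinical fact density", "anomalous values",
                            "utilization"),
    category_frequency = c("frequency distributions", "anomalous values",
                           "utilization"),
    conformance_value_sets = c("summary statistics",
                               "data representation error", "clinical care"),
    unbound = c("variable stratifications", "anomalous values",
                "clinical care"))
}

summary_for <- function(executor, variable) {
  switch(executor,
    completeness_trend = sprintf(
      "proportion of patients with at least one %s record per year", variable),
    same_day_concordance =
      "systolic and diastolic BP measurements present on the same day",
    pair_correlation = "correlation of systolic and diastolic blood pressures",
    unit_mapped_proportion = sprintf(
      "proportion of %s values with unit type mapped", variable),
    code_utilization = sprintf(
      "%s code frequency by site, one code per patient per calendar year",
      variable),
    med_timing =
      "days from cohort entry to first antihypertensive medication",
    geocode_granularity = "granularity of geocoded location data by site",
    value_distribution = sprintf("quantitative distribution of %s results",
                                 variable),
    attrition_funnel = "patients retained at each cohort attrition step",
    egfr_threshold_curve =
      "proportion of cohort with at least one eGFR below threshold",
    egfr_trajectory_medians = "median eGFR by year relative to cohort entry",
    yearly_count_trend = sprintf("%s record volume by calendar year", variable),
    per_patient_density = sprintf("%s records per patient", variable),
    category_frequency = sprintf("frequency distribution of %s categories",
                                 variable),
    conformance_value_sets = sprintf("value-set conformance of %s fields",
                                     variable),
    unbound = sprintf("stratified review of %s", variable))
}

# row helper: domains and categories are "|"-separated in the compact spec
catalog_rows <- function(round, spec) {
  rows <- lapply(seq_along(spec), function(i) {
    f <- strsplit(spec[[i]], "\\|")[[1]]
    # fields: domain(s, ';'-sep), variable, executor, categories(';'-sep)
    meta <- executor_meta(f[3])
    tibble::tibble(
      check_num = sprintf("%s-%03d", round, i),
      summary = summary_for(f[3], f[2]),
      check_type = meta[1],
      domains = f[1],
      variable = f[2],
      check_categories = f[4],
      dq_probe = meta[2],
      clinical_goal = meta[3],
      round = round,
      executor = f[3])
  })
  dplyr::bind_rows(rows)
}

dq1_spec <- function() list(
  "anthropometrics|vital:height|completeness_trend|completeness",
  "anthropometrics|vital:weight|completeness_trend|completeness",
  "anthropometrics|vital:height|per_patient_density|plausibility",
  "anthropometrics|vital:weight|per_patient_density|plausibility",
  "anthropometrics|vital:height|value_distribution|plausibility;conformance",
  "anthropometrics|vital:weight|value_distribution|conformance",
  "anthropometrics|vital:height|yearly_count_trend|completeness;plausibility",
  "anthropometrics|vitals|conformance_value_sets|conformance",
  "vital_signs|vital:systolic_bp|completeness_trend|completeness",
  "vital_signs|vital:diastolic_bp|completeness_trend|completeness",
  "vital_signs|vital:bp|same_day_concordance|concordance",
  "vital_signs|vital:bp|pair_correlation|concordance",
  "vital_signs|vital:systolic_bp|value_distribution|plausibility",
  "vital_signs|vital:diastolic_bp|value_distribution|plausibility",
  "vital_signs|vital:systolic_bp|per_patient_density|plausibility",
  "vital_signs|vital:systolic_bp|yearly_count_trend|completeness;plausibility",
  "diagnoses_conditions|condition:ckd|unbound|completeness",
  "diagnoses_conditions|condition:hypertension|unbound|completeness",
  "diagnoses_conditions|condition:ckd_vs_meds|unbound|concordance",
  "diagnoses_conditions|condition:ckd_vs_labs|unbound|concordance",
  "diagnoses_conditions|condition:code_mapping|unbound|conformance",
  "diagnoses_conditions|condition:code_utilization|unbound|conformance",
  "diagnoses_conditions|condition:ckd_density|unbound|plausibility;completeness",
  "diagnoses_conditions|condition:ckd_vs_visits|unbound|concordance",
  "laboratory|lab:serum_creatinine|completeness_trend|completeness",
  "laboratory|lab:serum_cystatin_c|completeness_trend|completeness",
  "laboratory|lab:urine_protein_quant|completeness_trend|completeness",
  "laboratory|lab:urine_creatinine|completeness_trend|completeness",
  "laboratory|lab:urine_protein_quant|unit_mapped_proportion|conformance",
  "laboratory|lab:serum_creatinine|unit_mapped_proportion|conformance",
  "laboratory|lab:serum_cystatin_c|unit_mapped_proportion|conformance",
  "laboratory|lab:urine_creatinine|unit_mapped_proportion|conformance",
  "laboratory|labs|conformance_value_sets|conformance",
  "laboratory|lab:urine_protein_quant|value_distribution|plausibility;conformance",
  "laboratory|lab:serum_creatinine|value_distribution|plausibility;conformance",
  "laboratory|lab:serum_cystatin_c|value_distribution|plausibility",
  "laboratory|lab:urine_creatinine|value_distribution|plausibility",
  "laboratory|lab:serum_creatinine|per_patient_density|plausibility",
  "laboratory|lab:serum_creatinine|yearly_count_trend|completeness;plausibility",
  "laboratory|lab:urine_protein_quant|yearly_count_trend|plausibility;completeness",
  "medications|med:acei_arb|completeness_trend|completeness",
  "medications|med:calcium_channel_blocker|completeness_trend|completeness",
  "medications|med:loop_diuretic|completeness_trend|completeness",
  "medications|med:thiazide|completeness_trend|completeness",
  "medications|med:beta_blocker|completeness_trend|completeness",
  "medications|med:antihypertensive|completeness_trend|completeness",
  "medications|med:acei_arb|per_patient_density|plausibility",
  "medications|med:calcium_channel_blocker|per_patient_density|plausibility",
  "medications|med:loop_diuretic|per_patient_density|plausibility",
  "medications|med:thiazide|per_patient_density|plausibility",
  "medications|med:beta_blocker|per_patient_density|plausibility",
  "medications|med:antihypertensive|per_patient_density|plausibility",
  "medications|med:acei_arb_vs_dx|unbound|concordance",
  "medications|med:ccb_vs_dx|unbound|concordance",
  "medications|med:loop_vs_dx|unbound|concordance",
  "medications|med:thiazide_vs_dx|unbound|concordance",
  "medications|med:beta_blocker_vs_dx|unbound|concordance",
  "medications|med:antihypertensive|yearly_count_trend|completeness;plausibility",
  "medications|med:antihypertensive|med_timing|plausibility;concordance",
  "medications|med:vs_procedures|unbound|concordance",
  "medications|meds|category_frequency|plausibility",
  "medications|meds|conformance_value_sets|conformance",
  "medications|med:code_mapping|unbound|conformance",
  "medications|med:acei_arb|yearly_count_trend|plausibility",
  "procedures|proc:chronic_dialysis|completeness_trend|completeness",
  "procedures|proc:kidney_transplant|completeness_trend|completeness",
  "procedures|proc:chronic_dialysis|code_utilization|conformance",
  "procedures|proc:kidney_transplant|code_utilization|conformance",
  "procedures|proc:chronic_dialysis|yearly_count_trend|plausibility;completeness",
  "procedures|proc:vs_visits|unbound|concordance",
  "procedures|procs|conformance_value_sets|conformance",
  "procedures|procs|category_frequency|plausibility",
  "other_eligibility|cohort:attrition|attrition_funnel|completeness;plausibility",
  "other_eligibility|visit:in_person|completeness_trend|completeness",
  "other_eligibility|derived:egfr|egfr_threshold_curve|plausibility",
  "other_eligibility|derived:egfr|per_patient_density|plausibility;concordance",
  "secular_trends|visit:any|yearly_count_trend|plausibility",
  "specialty|specialty:nephrology|completeness_trend|completeness;plausibility",
  "follow_up|visit:any|per_patient_density|completeness;plausibility")

dq2_spec <- function() list(
  "anthropometrics|vital:height|value_distribution|plausibility",
  "vital_signs|vital:systolic_bp|completeness_trend|completeness",
  "vital_signs|vital:diastolic_bp|completeness_trend|completeness",
  "vital_signs|vital:bp|same_day_concordance|concordance",
  "vital_signs|vital:bp|pair_correlation|consistency;concordance",
  "vital_signs|vital:systolic_bp|value_distribution|plausibility",
  "vital_signs|vital:diastolic_bp|value_distribution|plausibility",
  "vital_signs|vital:systolic_bp|per_patient_density|plausibility",
  "vital_signs|vital:diastolic_bp|per_patient_density|plausibility",
  "vital_signs|vital:systolic_bp|yearly_count_trend|consistency",
  "vital_signs|vital:diastolic_bp|yearly_count_trend|consistency",
  "vital_signs|vitals|conformance_value_sets|conformance",
  "vital_signs|vital:bp_age_percentile|unbound|plausibility",
  "vital_signs;visits|vital:bp_by_visit_type|unbound|plausibility",
  "diagnoses_conditions|condition:ckd|unbound|completeness",
  "diagnoses_conditions|condition:hypertension|unbound|completeness",
  "diagnoses_conditions|condition:ckd_vs_meds|unbound|concordance",
  "diagnoses_conditions|condition:code_mapping|unbound|conformance",
  "diagnoses_conditions|condition:code_utilization|unbound|conformance",
  "diagnoses_conditions|condition:ckd_density|unbound|plausibility",
  "diagnoses_conditions|condition:ckd_yearly|unbound|consistency",
  "diagnoses_conditions|conditions|unbound|plausibility",
  "diagnoses_conditions|condition:ckd_vs_labs|unbound|concordance",
  "geographic|patient:geocode_level|geocode_granularity|completeness",
  "geographic|patients|conformance_value_sets|conformance",
  "geographic|patient:geocode_level|category_frequency|plausibility;completeness",
  "geographic|patient:geocode_by_year|unbound|completeness",
  "geographic|patient:address_history|unbound|completeness",
  "geographic|patient:zip_validity|unbound|conformance",
  "geographic|patient:geocode_vs_region|unbound|plausibility",
  "geographic|patient:census_linkage|unbound|completeness",
  "laboratory|lab:serum_creatinine|completeness_trend|completeness",
  "laboratory|lab:serum_cystatin_c|completeness_trend|completeness",
  "laboratory|lab:urine_protein_quant|completeness_trend|completeness",
  "laboratory|lab:urine_creatinine|completeness_trend|completeness",
  "laboratory|lab:urine_protein_quant|unit_mapped_proportion|conformance",
  "laboratory|lab:urine_protein_quant|value_distribution|plausibility;completeness",
  "laboratory|lab:serum_creatinine|value_distribution|plausibility",
  "laboratory|lab:serum_cystatin_c|value_distribution|plausibility",
  "laboratory|lab:serum_creatinine|per_patient_density|plausibility;completeness",
  "laboratory|lab:serum_creatinine|yearly_count_trend|consistency",
  "laboratory|lab:urine_protein_quant|yearly_count_trend|consistency",
  "laboratory|labs|conformance_value_sets|conformance",
  "laboratory;derivations|derived:egfr|egfr_trajectory_medians|consistency",
  "derivations|derived:egfr|egfr_threshold_curve|plausibility",
  "derivations|derived:egfr|value_distribution|plausibility",
  "medications|med:antihypertensive|completeness_trend|completeness",
  "medications|meds|category_frequency|plausibility;completeness",
  "medications|med:antihypertensive|yearly_count_trend|completeness",
  "procedures|proc:chronic_dialysis|code_utilization|plausibility",
  "procedures|proc:kidney_transplant|code_utilization|plausibility",
  "procedures|proc:chronic_dialysis|completeness_trend|completeness",
  "procedures|proc:any|yearly_count_trend|consistency",
  "procedures|procs|conformance_value_sets|conformance",
  "eligibility|cohort:attrition|attrition_funnel|completeness;plausibility",
  "eligibility|cohort:age_at_entry|unbound|plausibility",
  "secular_trends|visit:any|completeness_trend|completeness",
  "medications;derivations|med:antihypertensive|med_timing|plausibility",
  "secular_trends|visit:any|yearly_count_trend|plausibility;consistency",
  "specialty|specialty:nephrology|completeness_trend|completeness",
  "specialty|visit:provider_specialty|category_frequency|plausibility;completeness",
  "cross_domain|cross:dx_lab_med|unbound|concordance",
  "visits|visit:visit_type|category_frequency|plausibility;completeness",
  "visits|visit:in_person|completeness_trend|completeness",
  "visits|visit:any|per_patient_density|plausibility;completeness")

catalog_cache <- new.env(parent = emptyenv())

#' Load a check catalog
#'
#' Returns the encoded catalog for one assessment round: DQ1 (aggregate-only
#' distributed round, 79 checks) or DQ2 (row-level round, 65 unique checks,
#' three spanning two domains). Entries carry the full taxonomy metadata
#' (check type, category or categories, data quality probe, clinical goal)
#' and the executor family binding used by [run_round()].
#'
#' @param round `"DQ1"` or `"DQ2"`.
#' @return Tibble with one row per check; `domains` and `check_categories`
#'   are `";"`-separated where a check has more than one.
#' @export
load_catalog <- function(round = c("DQ1", "DQ2")) {
  round <- match.arg(round)
  if (!is.null(catalog_cache[[round]])) return(catalog_cache[[round]])
  cat <- catalog_rows(round, if (round == "DQ1") dq1_spec() else dq2_spec())
  validate_catalog(cat)
  catalog_cache[[round]] <- cat
  cat
}

validate_catalog <- function(cat) {
  for (i in seq_len(nrow(cat))) {
    cats <- strsplit(cat$check_categories[i], ";")[[1]]
    doms <- strsplit(cat$domains[i], ";")[[1]]
    if (!all(cats %in% CHECK_CATEGORIES))
      stop(sprintf("catalog entry %s: bad check category", cat$check_num[i]))
    if (length(doms) < 1 || length(doms) > 2)
      stop(sprintf("catalog entry %s: a check has 1-2 domains",
                   cat$check_num[i]))
    if (!cat$check_type[i] %in% CHECK_TYPES)
      stop(sprintf("catalog entry %s: bad check type", cat$check_num[i]))
    if (!cat$dq_probe[i] %in% DQ_PROBES)
      stop(sprintf("catalog entry %s: bad data quality probe",
                   cat$check_num[i]))
    if (!cat$clinical_goal[i] %in% CLINICAL_GOALS)
      stop(sprintf("catalog entry %s: bad clinical goal", cat$check_num[i]))
    if (!cat$executor[i] %in% EXECUTORS)
      stop(sprintf("catalog entry %s: unknown executor", cat$check_num[i]))
  }
  if (anyDuplicated(cat$check_num))
    stop("duplicate check_num in catalog")
  invisible(cat)
}

#' Summarize a catalog's per-domain and per-category counts
#'
#' Domain counts tally each domain assignment (a dual-domain check counts in
#' both domains); category tallies likewise count every category a check
#' carries.
#'
#' @param catalog A catalog tibble from [load_catalog()].
#' @return List with `n_checks`, `domain_counts`, `category_counts`,
#'   `n_dual_domain`.
#' @export
catalog_summary <- function(catalog) {
  doms <- strsplit(catalog$domains, ";")
  cats <- strsplit(catalog$check_categories, ";")
  list(n_checks = nrow(catalog),
       domain_counts = table(unlist(doms)),
       category_counts = table(unlist(cats)),
       n_dual_domain = sum(lengths(doms) == 2))
}

#' Write a catalog to CSV
#'
#' @param catalog A catalog tibble.
#' @param path Output file.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_csv(catalog, path, progress = FALSE)
  invisible(path)
}
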