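# Turning check results into a prioritized, themed issue catalog, and
# tracking resolution across assessment rounds.

PRIORITIES <- c("urgent", "high", "medium", "low")
ISSUE_STATUSES <- c("open", "improvement", "clinical practice",
                    "EHR architecture", "source data", "not dq issue",
                    "prioritized other issues")
THEMES <- c("Anomalies affecting eligibility",
            "Variation in time of cohort entry",
            "Variation in clinical utilization",
            "Missingness of major variables",
            "Duplication of values",
            "Variation in code utilization",
            "Implausible value detection",
            "Implausible temporal trends",
            "Anomalous distribution of results",
            "Event sequencing anomalies",
            "Comparatively anomalous institutional clinical values")

# canonical element key for tier/theme lookups; accepts both internal
# variable tokens ("lab:serum_creatinine") and printed element names
# ("serum creatinine", "calcium channel blockers")
canon_element <- function(e) {
  k <- tolower(trimws(e))
  k <- gsub("[ /]+", "_", k)
  k <- sub("^(lab|vital|med|proc|patient|visit|specialty|condition|derived|cohort):",
           "", k)
  syn <- c(quantitative_urine_protein_measurement = "urine_protein_quant",
           urine_protein = "urine_protein_quant",
           serum_cystatin = "serum_cystatin_c",
           serum_cystatin_c = "serum_cystatin_c",
           calcium_channel_blockers = "calcium_channel_blocker",
           loop_diuretics = "loop_diuretic",
           systolic = "systolic_bp",
           diastolic = "diastolic_bp",
           nephrology = "nephrology_specialty",
           nephrology_specialty = "nephrology_specialty",
           egfr = "egfr")
  ifelse(k %in% names(syn), unname(syn[k]), k)
}

normalize_dq_issue <- function(x) {
  map <- c("counts high" = "high counts", "counts low" = "low counts",
           "values low" = "outlier values", "values high" = "outlier values")
  x <- tolower(trimws(x))
  ifelse(x %in% names(map), unname(map[x]), x)
}

#' Default variable tiers for prioritization
#'
#' Eligibility criteria outrank main exposures and outcomes, which outrank
#' covariates.
#'
#' @return Named list with `eligibility` and `exposure` element keys; unlisted
#'   elements are covariates.
#' @export
default_variable_tiers <- function() {
  list(eligibility = c("serum_creatinine", "height", "egfr",
                       "nephrology_specialty", "in_person", "any",
                       "cohort_entry", "chronic_dialysis",
                       "kidney_transplant"),
       exposure = c("systolic_bp", "diastolic_bp"))
}

element_tier <- function(key, tiers = default_variable_tiers()) {
  dplyr::case_when(
    grepl("^attrition_step", key) ~ "eligibility",
    key %in% tiers$eligibility ~ "eligibility",
    key %in% tiers$exposure ~ "exposure",
    TRUE ~ "covariate")
}

#' Assign priorities to issues
#'
#' The decision table, calibrated to the study's published site summaries:
#' attrition-step count anomalies and out-of-range values on eligibility-tier
#' elements are urgent, as is total missingness of an eligibility element;
#' interior-year missingness of eligibility/exposure elements is high;
#' expected-sparse elements and medication count anomalies are low; late
#' data onset, secondary-cohort counts, and remaining distributional
#' anomalies are medium.
#'
#' @param issues Tibble with columns `domain`, `element`, `dq_issue`, and
#'   optionally `missing_kind` (`"interior"`, `"leading"`, `"total"`).
#' @param variable_tiers See [default_variable_tiers()].
#' @param expected_sparse Character vector of expected-sparse element keys.
#' @return Character vector of priorities, one per issue row.
#' @export
assign_priority <- function(issues,
                            variable_tiers = default_variable_tiers(),
                            expected_sparse = analysis_config()$expected_sparse) {
  key <- canon_element(issues$element)
  dq <- normalize_dq_issue(issues$dq_issue)
  tier <- element_tier(key, variable_tiers)
  domain <- gsub("[ ]+", "_", tolower(issues$domain))
  mk <- if ("missing_kind" %in% names(issues)) issues$missing_kind
        else rep(NA_character_, nrow(issues))
  sparse <- canon_element(expected_sparse)
  counts <- dq %in% c("high counts", "low counts")
  dplyr::case_when(
    counts & grepl("^attrition_step", key) ~ "urgent",
    dq == "outlier values" & tier == "eligibility" ~ "urgent",
    dq == "missingness" & key %in% sparse ~ "low",
    dq == "missingness" &
      (key == "cohort_entry" | mk %in% "leading") ~ "medium",
    dq == "missingness" & mk %in% "total" & tier == "eligibility" ~ "urgent",
    dq == "missingness" & tier %in% c("eligibility", "exposure") ~ "high",
    dq == "missingness" ~ "medium",
    counts & domain == "medications" ~ "low",
    counts & domain %in% c("cohort_definition", "cohort definition") ~ "medium",
    counts ~ "medium",
    dq %in% c("high spike", "low spike") ~ "medium",
    dq %in% c("atypical numeric distribution", "atypical code distribution",
              "discordant values", "mapping error", "outlier values") ~ "medium",
    TRUE ~ "low")
}

#' Assign themes to issues
#'
#' Many-to-one lookup from (domain, element, issue code) to the published
#' theme vocabulary; an issue may carry several themes and always receives at
#' least one. Themes are returned `";"`-joined.
#'
#' @inheritParams assign_priority
#' @return Character vector of `";"`-joined themes.
#' @export
assign_theme <- function(issues,
                         variable_tiers = default_variable_tiers()) {
  key <- canon_element(issues$element)
  dq <- normalize_dq_issue(issues$dq_issue)
  tier <- element_tier(key, variable_tiers)
  domain <- gsub("[ ]+", "_", tolower(issues$domain))
  mk <- if ("missing_kind" %in% names(issues)) issues$missing_kind
        else rep(NA_character_, nrow(issues))
  vapply(seq_len(nrow(issues)), function(i) {
    th <- character()
    if (grepl("^attrition_step", key[i]) ||
        domain[i] %in% c("cohort_definition", "cohort definition") ||
        tier[i] == "eligibility")
      th <- c(th, "Anomalies affecting eligibility")
    if (dq[i] == "missingness") {
      if (key[i] == "cohort_entry" || mk[i] %in% "leading")
        th <- c(th, "Variation in time of cohort entry")
      else th <- c(th, "Missingness of major variables")
    }
    if (dq[i] == "high counts" &&
        domain[i] %in% c("anthropometrics", "blood_pressure", "vital_signs"))
      th <- c(th, "Duplication of values")
    if (dq[i] %in% c("high spike", "low spike"))
      th <- c(th, "Implausible temporal trends")
    if (dq[i] == "outlier values") {
      if (key[i] == "antihypertensive")
        th <- c(th, "Event sequencing anomalies")
      else th <- c(th, "Implausible value detection")
    }
    if (dq[i] == "atypical numeric distribution")
      th <- c(th, "Anomalous distribution of results")
    if (dq[i] == "atypical code distribution") {
      th <- c(th, "Variation in code utilization")
      if (grepl("^visit", issues$element[i]))
        th <- c(th, "Variation in clinical utilization")
    }
    if (dq[i] == "mapping error")
      th <- c(th, if (domain[i] %in% c("demographics", "patients"))
        "Anomalies affecting eligibility" else "Anomalous distribution of results")
    if (dq[i] == "discordant values")
      th <- c(th, "Comparatively anomalous institutional clinical values")
    if (length(th) == 0)
      th <- "Comparatively anomalous institutional clinical values"
    paste(unique(th), collapse = ";")
  }, character(1))
}

variable_domain <- function(variable) {
  key <- canon_element(variable)
  dplyr::case_when(
    key %in% c("height", "weight") ~ "anthropometrics",
    key %in% c("systolic_bp", "diastolic_bp", "bp") ~ "blood_pressure",
    grepl("^lab:", variable) ~ "laboratory tests",
    grepl("^med:", variable) ~ "medications",
    grepl("^proc:", variable) ~ "procedures",
    variable == "patient:geocode_level" ~ "geographic",
    grepl("^patient:", variable) ~ "demographics",
    grepl("^specialty:", variable) ~ "specialty",
    grepl("^visit", variable) ~ "utilization",
    key == "egfr" ~ "derivations",
    grepl("^attrition_step", key) ~ "cohort definition",
    key == "cohort_entry" ~ "cohort entry",
    TRUE ~ "other")
}

#' Tukey-fence outliers across sites
#'
#' Type-7 quartiles; values outside `[Q1 - k*IQR, Q3 + k*IQR]` are flagged,
#' subject to a minimum relative deviation from the cross-site median so that
#' near-constant metrics with tiny IQRs do not flag sampling noise. Fewer
#' than `config$min_sites` sites yields no result.
#'
#' @param values Tibble with `site_id` and `value`.
#' @param config An [analysis_config()].
#' @return Tibble of flagged sites (`site_id`, `value`, `direction`,
#'   `fence_lo`, `fence_hi`), possibly empty.
#' @export
fence_outliers <- function(values, config = analysis_config()) {
  empty <- tibble::tibble(site_id = character(), value = numeric(),
                          direction = character(), fence_lo = numeric(),
                          fence_hi = numeric())
  x <- values$value[is.finite(values$value)]
  if (nrow(values) < config$min_sites || length(x) < config$min_sites)
    return(empty)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - config$fence_multiplier * iqr
  hi <- q[2] + config$fence_multiplier * iqr
  med <- stats::median(x)
  rel_ok <- abs(values$value - med) >
    config$min_rel_dev * max(abs(med), 1e-9)
  out_lo <- is.finite(values$value) & values$value < lo & rel_ok
  out_hi <- is.finite(values$value) & values$value > hi & rel_ok
  flagged <- values[out_lo | out_hi, c("site_id", "value")]
  if (nrow(flagged) == 0) return(empty)
  flagged$direction <- ifelse(flagged$value >
                                stats::median(values$value), "high", "low")
  flagged$fence_lo <- lo
  flagged$fence_hi <- hi
  flagged
}

issue_row <- function(site_id, domain, element, dq_issue, info, report_ref,
                      check_num = NA_character_, stratum = NA_character_,
                      metric = NA_real_, missing_kind = NA_character_) {
  tibble::tibble(site_id = site_id, domain = domain, element = element,
                 dq_issue = dq_issue, info = info, report_ref = report_ref,
                 check_num = check_num, stratum = stratum, metric = metric,
                 missing_kind = missing_kind)
}

report_ref_for <- function(executor) {
  switch(executor,
    completeness_trend = "fig_completeness_trends",
    same_day_concordance = "fig_bp_concordance",
    pair_correlation = "fig_bp_correlation",
    unit_mapped_proportion = "tab_unit_mapping",
    code_utilization = "fig_code_matrix",
    med_timing = "fig_med_timing",
    geocode_granularity = "fig_geocode",
    value_distribution = "fig_distributions",
    attrition_funnel = "fig_attrition",
    egfr_threshold_curve = "fig_threshold_curves",
    egfr_trajectory_medians = "fig_egfr_trajectory",
    yearly_count_trend = "fig_volume_trends",
    per_patient_density = "fig_density",
    category_frequency = "fig_category_frequencies",
    conformance_value_sets = "tab_conformance",
    "tab_conformance")
}

#' Detect missing calendar years in completeness trends
#'
#' A site-variable with zero proportion in one or more years strictly inside
#' its data span yields a missingness issue listing the years; a run of
#' missing years at the start of the span yields a late-onset issue instead
#' (for the encounter variable the element is the cohort entry itself); a
#' fully empty span yields a total-missingness issue.
#'
#' @param trend_results Check results from [completeness_trend()] (with
#'   `check_num`).
#' @param catalog Catalog tibble (to resolve variables).
#' @param config An [analysis_config()].
#' @return Issue tibble (without priority/themes).
#' @export
detect_missing_years <- function(trend_results, catalog,
                                 config = analysis_config()) {
  out <- list()
  x <- dplyr::inner_join(trend_results,
                         catalog[, c("check_num", "variable")],
                         by = "check_num")
  for (grp in split(x, list(x$check_num, x$site_id), drop = TRUE)) {
    grp <- grp[order(as.integer(grp$stratum)), ]
    years <- as.integer(grp$stratum)
    zero <- grp$value == 0 & grp$denominator > 0
    if (!any(zero)) next
    variable <- grp$variable[1]
    site <- grp$site_id[1]
    ref <- report_ref_for("completeness_trend")
    yrs <- function(y) paste0("calendar years missing: ",
                              paste(y, collapse = ", "))
    if (all(zero)) {
      out[[length(out) + 1]] <- issue_row(
        site, variable_domain(variable), variable, "missingness",
        yrs(years), ref, grp$check_num[1], "all", 0, "total")
      next
    }
    lead_len <- which(!zero)[1] - 1
    if (lead_len > 0) {
      lead_years <- years[seq_len(lead_len)]
      elem <- if (variable == "visit:any") "cohort_entry" else variable
      dom <- if (variable == "visit:any") "cohort entry"
             else variable_domain(variable)
      out[[length(out) + 1]] <- issue_row(
        site, dom, elem, "missingness", yrs(lead_years), ref,
        grp$check_num[1], as.character(lead_years[1]), 0, "leading")
    }
    interior <- zero & seq_along(zero) > lead_len
    if (any(interior)) {
      out[[length(out) + 1]] <- issue_row(
        site, variable_domain(variable), variable, "missingness",
        yrs(years[interior]), ref, grp$check_num[1],
        as.character(years[interior][1]), 0, "interior")
    }
  }
  dplyr::bind_rows(out)
}

#' Detect yearly volume spikes by leave-one-out z-score
#'
#' For each site-series of at least four yearly counts, each year is scored
#' against the mean and SD of the remaining years, with the SD floored at a
#' fraction of the leave-one-out mean; |z| above the threshold yields a high
#' or low spike issue naming the years.
#'
#' @param yearly_results Check results from [yearly_count_trend()].
#' @param catalog Catalog tibble.
#' @param config An [analysis_config()].
#' @return Issue tibble (without priority/themes).
#' @export
detect_spikes <- function(yearly_results, catalog,
                          config = analysis_config()) {
  out <- list()
  x <- dplyr::inner_join(yearly_results,
                         catalog[, c("check_num", "variable")],
                         by = "check_num")
  for (grp in split(x, list(x$check_num, x$site_id), drop = TRUE)) {
    if (nrow(grp) < 4) next
    grp <- grp[order(as.integer(grp$stratum)), ]
    v <- grp$value
    z <- vapply(seq_along(v), function(i) {
      m <- mean(v[-i]); s <- stats::sd(v[-i])
      s <- max(s, config$sd_floor_frac * abs(m))
      if (s == 0) return(0)
      (v[i] - m) / s
    }, numeric(1))
    variable <- grp$variable[1]
    ref <- report_ref_for("yearly_count_trend")
    for (dir in c("high", "low")) {
      hit <- if (dir == "high") z > config$spike_z else z < -config$spike_z
      if (!any(hit)) next
      yrs <- grp$stratum[hit]
      out[[length(out) + 1]] <- issue_row(
        grp$site_id[1], variable_domain(variable), variable,
        paste(dir, "spike"),
        sprintf("calendar years with %s spike: %s", dir,
                paste(yrs, collapse = ", ")),
        ref, grp$check_num[1], yrs[1], v[hit][1])
    }
  }
  dplyr::bind_rows(out)
}

#' Detect cross-site outliers for one check's per-site values
#'
#' Applies the Tukey fence (see [fence_outliers()]) and emits one issue per
#' flagged site with the check family's issue codes.
#'
#' @param values Tibble with `site_id` and `value` (one row per site).
#' @param element Data element name for the issues.
#' @param domain Clinical/data domain for the issues.
#' @param dq_issue_high,dq_issue_low Issue codes for high/low flags.
#' @param report_ref Report reference label.
#' @param config An [analysis_config()].
#' @param check_num,stratum Provenance fields carried into the issue.
#' @return Issue tibble (without priority/themes).
#' @export
detect_site_outliers <- function(values, element, domain,
                                 dq_issue_high = "high counts",
                                 dq_issue_low = "low counts",
                                 report_ref = "tab_conformance",
                                 config = analysis_config(),
                                 check_num = NA_character_,
                                 stratum = NA_character_) {
  fl <- fence_outliers(values, config)
  if (nrow(fl) == 0) return(issue_row(character(), character(), character(),
                                      character(), character(), character()))
  issue_row(fl$site_id, domain, element,
            ifelse(fl$direction == "high", dq_issue_high, dq_issue_low),
            sprintf("value %.4g outside fence [%.4g, %.4g]", fl$value,
                    fl$fence_lo, fl$fence_hi),
            report_ref, check_num, stratum, fl$value)
}

#' Detect distributional anomalies in value-distribution results
#'
#' A top value-mass fraction above the threshold yields an atypical numeric
#' distribution issue; any out-of-range fraction yields an outlier-values
#' issue.
#'
#' @param dist_results Check results from [value_distribution()].
#' @param catalog Catalog tibble.
#' @param config An [analysis_config()].
#' @return Issue tibble (without priority/themes).
#' @export
detect_value_anomalies <- function(dist_results, catalog,
                                   config = analysis_config()) {
  x <- dplyr::inner_join(dist_results,
                         catalog[, c("check_num", "variable")],
                         by = "check_num")
  ref <- report_ref_for("value_distribution")
  out <- list()
  tm <- x[x$stratum == "top_mass" &
            x$value > config$mass_fraction_threshold, ]
  if (nrow(tm) > 0)
    out[[length(out) + 1]] <- issue_row(
      tm$site_id, variable_domain(tm$variable), tm$variable,
      "atypical numeric distribution",
      sprintf("fraction %.3f of records share one exact value", tm$value),
      ref, tm$check_num, "top_mass", tm$value)
  oor <- x[x$stratum == "out_of_range" & x$value > 0, ]
  if (nrow(oor) > 0)
    out[[length(out) + 1]] <- issue_row(
      oor$site_id, variable_domain(oor$variable), oor$variable,
      "outlier values",
      sprintf("fraction %.3f of values outside physiologic bounds",
              oor$value),
      ref, oor$check_num, "out_of_range", oor$value)
  dplyr::bind_rows(out)
}

#' Detect all issues from one round's outputs
#'
#' Routes every executor family's results to its detector, converts
#' conformance findings to mapping-error issues, assigns priorities and
#' themes, and numbers the issues deterministically.
#'
#' @param round_output Result of [run_round()].
#' @param config An [analysis_config()].
#' @return Issue tibble with `issue_id`, `site_id`, `priority`, `domain`,
#'   `element`, `dq_issue`, `info`, `report_ref`, `themes`, `status` plus
#'   provenance columns (`check_num`, `stratum`, `metric`, `missing_kind`).
#' @export
detect_issues <- function(round_output, config = analysis_config()) {
  results <- round_output$results
  catalog <- round_output$catalog
  ex_of <- stats::setNames(catalog$executor, catalog$check_num)
  var_of <- stats::setNames(catalog$variable, catalog$check_num)
  res_ex <- ex_of[results$check_num]
  out <- list()
  add <- function(x) if (!is.null(x) && nrow(x) > 0)
    out[[length(out) + 1]] <<- x

  add(detect_missing_years(results[res_ex == "completeness_trend", ],
                           catalog, config))
  add(detect_spikes(results[res_ex == "yearly_count_trend", ], catalog,
                    config))
  add(detect_value_anomalies(results[res_ex == "value_distribution", ],
                             catalog, config))

  # discordant blood pressures
  pc <- results[res_ex == "pair_correlation", ]
  bad <- pc[pc$value < config$correlation_floor, ]
  add(if (nrow(bad) > 0) issue_row(
    bad$site_id, "blood_pressure", "vital:bp", "discordant values",
    sprintf("systolic/diastolic correlation r = %.2f below %.2f",
            bad$value, config$correlation_floor),
    report_ref_for("pair_correlation"), bad$check_num, "all", bad$value))

  # antihypertensive timing: majority starting before entry
  mt <- results[res_ex == "med_timing" & results$stratum == "frac_negative", ]
  bad <- mt[mt$value > 0.5, ]
  add(if (nrow(bad) > 0) issue_row(
    bad$site_id, "medications", "med:antihypertensive", "outlier values",
    sprintf("fraction %.2f of cohort started antihypertensive before entry",
            bad$value),
    report_ref_for("med_timing"), bad$check_num, "frac_negative", bad$value))

  # cross-site fences, per executor family and stratum
  fence_plan <- list(
    per_patient_density = c("high counts", "low counts"),
    attrition_funnel = c("high counts", "low counts"),
    egfr_threshold_curve = c("high counts", "low counts"),
    geocode_granularity = c("atypical code distribution",
                            "atypical code distribution"),
    code_utilization = c("atypical code distribution",
                         "atypical code distribution"),
    category_frequency = c("atypical code distribution",
                           "atypical code distribution"),
    unit_mapped_proportion = c("mapping error", "mapping error"),
    same_day_concordance = c("missingness", "missingness"))
  for (fam in names(fence_plan)) {
    fr <- results[res_ex == fam & !is.na(res_ex), ]
    if (nrow(fr) == 0) next
    codes <- fence_plan[[fam]]
    for (grp in split(fr, list(fr$check_num, fr$stratum), drop = TRUE)) {
      if (fam == "attrition_funnel") {
        if (grp$stratum[1] == "step_00") next
        vals <- tibble::tibble(site_id = grp$site_id,
                               value = grp$value / grp$denominator)
        elem <- sub("step", "attrition_step", grp$stratum[1])
        dom <- "cohort definition"
      } else {
        vals <- grp[, c("site_id", "value")]
        elem <- var_of[[grp$check_num[1]]]
        dom <- variable_domain(elem)
      }
      iss <- detect_site_outliers(vals, elem, dom, codes[1], codes[2],
                                  report_ref_for(fam), config,
                                  grp$check_num[1], grp$stratum[1])
      # unit mapping and same-day coverage only flag low sites
      if (fam %in% c("unit_mapped_proportion", "same_day_concordance") &&
          nrow(iss) > 0)
        iss <- iss[iss$metric < stats::median(vals$value), ]
      add(iss)
    }
  }

  # conformance findings -> issues
  conf <- round_output$conformance
  if (!is.null(conf) && nrow(conf) > 0) {
    prefix <- c(patients = "patient:", visits = "visit:", vitals = "vital:",
                labs = "lab:", meds = "med:", procs = "proc:")
    elem <- ifelse(grepl("^unit:", conf$field),
                   paste0("lab:", sub("^unit:", "", conf$field)),
                   paste0(prefix[conf$domain], conf$field))
    dom <- ifelse(conf$domain == "patients", "demographics", conf$domain)
    add(issue_row(conf$site_id, dom, elem, conf$dq_issue,
                  sprintf("%d non-conformant records in %s.%s", conf$count,
                          conf$domain, conf$field),
                  "tab_conformance", NA_character_, conf$field, conf$count))
  }

  issues <- dplyr::bind_rows(out)
  if (nrow(issues) == 0) {
    issues <- issue_row(character(), character(), character(), character(),
                        character(), character())
    issues$issue_id <- character(); issues$priority <- character()
    issues$themes <- character(); issues$status <- character()
    return(issues[, c("issue_id", "site_id", "priority", "domain", "element",
                      "dq_issue", "info", "report_ref", "themes", "status",
                      "check_num", "stratum", "metric", "missing_kind")])
  }
  issues <- dplyr::distinct(issues, .data$site_id, .data$element,
                            .data$dq_issue, .data$info, .keep_all = TRUE)
  issues$priority <- assign_priority(issues,
                                     expected_sparse = config$expected_sparse)
  issues$themes <- assign_theme(issues)
  issues$status <- "open"
  issues <- issues[order(match(issues$priority, PRIORITIES), issues$site_id,
                         issues$element, issues$dq_issue), ]
  issues$issue_id <- sprintf("I%03d", seq_len(nrow(issues)))
  issues[, c("issue_id", "site_id", "priority", "domain", "element",
             "dq_issue", "info", "report_ref", "themes", "status",
             "check_num", "stratum", "metric", "missing_kind")]
}

#' Compare two rounds and track issue resolution
#'
#' Re-runs detection on the after-round outputs; a before-issue is resolved
#' when the metric that triggered it no longer triggers (no issue with the
#' same site, element and issue code is detected on the after results).
#' Resolved issues get status `"improvement"`; unresolved issues keep their
#' annotated status.
#'
#' @param issues_before Issue tibble from the earlier round.
#' @param round_output_after [run_round()] output for the later round.
#' @param config An [analysis_config()].
#' @return Tibble with `issue_id`, `site_id`, `element`, `dq_issue`,
#'   `metric_before`, `metric_after`, `resolved`, `status`.
#' @export
compare_rounds <- function(issues_before, round_output_after,
                           config = analysis_config()) {
  issues_after <- detect_issues(round_output_after, config)
  compare_round_tables(issues_before, issues_after,
                       round_output_after$results)
}

#' Run one full assessment round: checks plus issue detection
#'
#' @param dataset A `dq_dataset`.
#' @param round `"DQ1"` or `"DQ2"`.
#' @param config An [analysis_config()].
#' @return The [run_round()] output with an `issues` element added.
#' @export
dq_round <- function(dataset, round = c("DQ1", "DQ2"),
                     config = analysis_config()) {
  out <- run_round(dataset, round, config)
  out$issues <- detect_issues(out, config)
  out
}
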