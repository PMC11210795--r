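# Check executors and the two execution modes: DQ1 computes each site's
# aggregates from that site's records in isolation; DQ2 computes from pooled
# rows. For every dual-mode check the per-site values agree exactly.

ANTIHYPERTENSIVES <- c("acei_arb", "calcium_channel_blocker", "loop_diuretic",
                       "thiazide", "beta_blocker")

check_result <- function(site_id = character(), stratum = character(),
                         value = numeric(), denominator = numeric()) {
  tibble::tibble(site_id = site_id, stratum = as.character(stratum),
                 value = value, denominator = denominator)
}

# Resolve a variable token ("domain:code") to its records.
# Returns a tibble with at least site_id, patient_id and (except for
# patient-level variables) date.
select_records <- function(dataset, variable) {
  parts <- strsplit(variable, ":", fixed = TRUE)[[1]]
  domain <- parts[1]; code <- if (length(parts) > 1) parts[2] else "any"
  switch(domain,
    lab = dataset$labs[dataset$labs$lab == code, ],
    vital = dataset$vitals[dataset$vitals$measure == code, ],
    med = if (code == "antihypertensive")
      dataset$meds[dataset$meds$drug_class %in% ANTIHYPERTENSIVES, ]
    else dataset$meds[dataset$meds$drug_class == code, ],
    proc = if (code == "any") dataset$procs
    else dataset$procs[dataset$procs$code_group == code, ],
    visit = if (code == "any") dataset$visits
    else if (code == "in_person") dataset$visits[dataset$visits$in_person %in% TRUE, ]
    else dataset$visits[dataset$visits$visit_type == code, ],
    specialty = dataset$visits[dataset$visits$provider_specialty == code, ],
    stop(sprintf("no selector for variable: %s", variable), call. = FALSE))
}

# patients with >= 1 visit per site-year: the completeness denominator
active_patients <- function(dataset) {
  v <- dataset$visits
  tibble::tibble(site_id = v$site_id, patient_id = v$patient_id,
                 year = year_of(v$date)) |>
    dplyr::distinct()
}

site_years <- function(dataset) {
  sp <- dataset$site_span[!is.na(dataset$site_span$first_year), ]
  if (nrow(sp) == 0)
    return(tibble::tibble(site_id = character(), year = integer()))
  dplyr::bind_rows(lapply(seq_len(nrow(sp)), function(i) {
    tibble::tibble(site_id = sp$site_id[i],
                   year = seq(sp$first_year[i], sp$last_year[i]))
  }))
}

#' Completeness trend: per-site per-year proportion of patients with a record
#'
#' For most variables the denominator is the site's patients active (>= 1
#' visit) in that year, over the site's data span. For the encounter variable
#' `visit:any` the denominator is all of the site's patients and the strata
#' are every year of the study interval, which is the surface used to detect
#' late data onset.
#'
#' @param dataset A `dq_dataset`.
#' @param variable Variable token, e.g. `"lab:serum_creatinine"`.
#' @param config An [analysis_config()].
#' @return Check-result tibble (`site_id`, `stratum` = year, `value` =
#'   proportion, `denominator`).
#' @export
completeness_trend <- function(dataset, variable, config = analysis_config()) {
  r <- select_records(dataset, variable)
  if (variable == "visit:any") {
    denom <- dataset$patients |>
      dplyr::count(.data$site_id, name = "denominator")
    years <- tidyr::expand_grid(
      site_id = sort(unique(dataset$patients$site_id)),
      year = seq(config$study_interval[1], config$study_interval[2]))
    grid <- dplyr::left_join(years, denom, by = "site_id")
  } else {
    act <- active_patients(dataset) |>
      dplyr::count(.data$site_id, .data$year, name = "denominator")
    grid <- dplyr::left_join(site_years(dataset), act,
                             by = c("site_id", "year"))
    grid$denominator[is.na(grid$denominator)] <- 0L
  }
  num <- tibble::tibble(site_id = r$site_id, patient_id = r$patient_id,
                        year = year_of(r$date)) |>
    dplyr::distinct() |>
    dplyr::count(.data$site_id, .data$year, name = "n_with")
  out <- dplyr::left_join(grid, num, by = c("site_id", "year"))
  out$n_with[is.na(out$n_with)] <- 0L
  out <- out[out$denominator > 0, ]
  check_result(out$site_id, out$year, out$n_with / out$denominator,
               out$denominator)
}

#' Same-day systolic/diastolic concordance
#'
#' Per site, the fraction of patient-days having a systolic value that also
#' have a diastolic value.
#'
#' @inheritParams completeness_trend
#' @return Check-result tibble (stratum `"all"`).
#' @export
same_day_concordance <- function(dataset, config = analysis_config()) {
  v <- dataset$vitals
  sys_days <- v[v$measure == "systolic_bp", c("site_id", "patient_id", "date")] |>
    dplyr::distinct()
  dia_days <- v[v$measure == "diastolic_bp", c("patient_id", "date")] |>
    dplyr::distinct() |>
    dplyr::mutate(has_dia = TRUE)
  x <- dplyr::left_join(sys_days, dia_days, by = c("patient_id", "date"))
  out <- x |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(value = mean(!is.na(.data$has_dia)),
                     denominator = dplyr::n(), .groups = "drop")
  check_result(out$site_id, "all", out$value, out$denominator)
}

#' Pearson correlation of same-day systolic and diastolic means
#'
#' Same-day patient means are used when multiple measurements exist; sites
#' with fewer concordant patient-days than `config$min_pairs` yield no row.
#'
#' @inheritParams completeness_trend
#' @return Check-result tibble (stratum `"all"`, value = r, denominator =
#'   number of pairs).
#' @export
pair_correlation <- function(dataset, config = analysis_config()) {
  v <- dataset$vitals[dataset$vitals$measure %in%
                        c("systolic_bp", "diastolic_bp"), ]
  means <- v |>
    dplyr::group_by(.data$site_id, .data$patient_id, .data$date,
                    .data$measure) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "measure", values_from = "value")
  if (!all(c("systolic_bp", "diastolic_bp") %in% names(means)))
    return(check_result())
  pairs <- means[!is.na(means$systolic_bp) & !is.na(means$diastolic_bp), ]
  out <- pairs |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      value = if (dplyr::n() >= config$min_pairs &&
                  stats::sd(.data$systolic_bp) > 0 &&
                  stats::sd(.data$diastolic_bp) > 0)
        stats::cor(.data$systolic_bp, .data$diastolic_bp) else NA_real_,
      .groups = "drop") |>
    dplyr::filter(!is.na(.data$value))
  check_result(out$site_id, "all", out$value, out$n)
}

#' Proportion of a lab's records with a mapped unit
#'
#' @param dataset A `dq_dataset`.
#' @param lab Lab code.
#' @return Check-result tibble; sites with no records of the lab yield no row.
#' @export
unit_mapped_proportion <- function(dataset, lab) {
  r <- dataset$labs[dataset$labs$lab == lab, ]
  if (nrow(r) == 0) return(check_result())
  out <- r |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(value = mean(.data$mapped_unit),
                     denominator = dplyr::n(), .groups = "drop")
  check_result(out$site_id, "all", out$value, out$denominator)
}

#' Code-utilization matrix with patient-year deduplication
#'
#' Each (patient, code, calendar year) is counted once; a cell is the number
#' of distinct cohort patient-years carrying the code at the site divided by
#' the site's cohort patient-years (years in which a member had any visit).
#' Codes whose pooled prevalence is below `config$prevalence_min` are dropped;
#' sites with zero occurrences of a retained code keep an explicit zero row.
#'
#' @param dataset A `dq_dataset`.
#' @param cohort Cohort tibble from [apply_attrition()].
#' @param code_group Procedure code group, e.g. `"chronic_dialysis"`.
#' @param config An [analysis_config()].
#' @return Check-result tibble (stratum = code, value = proportion,
#'   denominator = cohort patient-years).
#' @export
code_utilization <- function(dataset, cohort, code_group,
                             config = analysis_config()) {
  finalize_code_utilization(code_utilization_raw(dataset, cohort, code_group),
                            config)
}

# Per-site aggregates of the code matrix before the cross-site prevalence
# filter: one row per (site, code) observed at the site plus a sentinel
# "_patient_years" row per site carrying the denominator. This is what a
# distributed aggregate-only query can return; the prevalence filter and the
# zero-row completion are coordinating-center post-processing
# (finalize_code_utilization), so both execution modes share them.
code_utilization_raw <- function(dataset, cohort, code_group) {
  if (nrow(cohort) == 0) return(check_result())
  py <- active_patients(dataset) |>
    dplyr::filter(.data$patient_id %in% cohort$patient_id) |>
    dplyr::count(.data$site_id, name = "patient_years")
  pr <- dataset$procs[dataset$procs$code_group == code_group &
                        dataset$procs$patient_id %in% cohort$patient_id, ]
  cell <- tibble::tibble(site_id = pr$site_id, patient_id = pr$patient_id,
                         code = pr$code, year = year_of(pr$date)) |>
    dplyr::distinct() |>
    dplyr::count(.data$site_id, .data$code, name = "n_py") |>
    dplyr::left_join(py, by = "site_id")
  dplyr::bind_rows(
    check_result(py$site_id, "_patient_years", py$patient_years,
                 py$patient_years),
    check_result(cell$site_id, cell$code, cell$n_py, cell$patient_years)) |>
    dplyr::arrange(.data$site_id, .data$stratum)
}

finalize_code_utilization <- function(raw, config = analysis_config()) {
  if (nrow(raw) == 0) return(check_result())
  keep_cols <- setdiff(names(raw), c("site_id", "stratum", "value",
                                     "denominator"))
  py <- raw[raw$stratum == "_patient_years", c("site_id", "value")]
  names(py)[2] <- "patient_years"
  cell <- raw[raw$stratum != "_patient_years", ]
  if (nrow(cell) == 0) return(check_result())
  pooled <- tapply(cell$value, cell$stratum, sum)
  keep <- names(pooled)[pooled / sum(py$patient_years) >=
                          config$prevalence_min]
  if (length(keep) == 0) return(check_result())
  grid <- tidyr::expand_grid(site_id = py$site_id, stratum = sort(keep)) |>
    dplyr::left_join(cell[, c("site_id", "stratum", "value")],
                     by = c("site_id", "stratum")) |>
    dplyr::left_join(py, by = "site_id")
  grid$value[is.na(grid$value)] <- 0
  out <- check_result(grid$site_id, grid$stratum,
                      grid$value / grid$patient_years, grid$patient_years)
  for (col in keep_cols) out[[col]] <- raw[[col]][1]
  out
}

#' Timing of first antihypertensive relative to cohort entry
#'
#' Per cohort member, days from cohort entry date to the first
#' antihypertensive order; members with no antihypertensive are omitted and
#' the member denominator is reported. Summarized per site as quartiles and
#' the fraction starting before entry.
#'
#' @inheritParams code_utilization
#' @return Check-result tibble with strata `q1`, `median`, `q3`,
#'   `frac_negative` (denominator = members with a medication) and
#'   `n_with_med` (denominator = cohort members).
#' @export
med_timing <- function(dataset, cohort, config = analysis_config()) {
  if (nrow(cohort) == 0) return(check_result())
  m <- dataset$meds[dataset$meds$drug_class %in% ANTIHYPERTENSIVES &
                      dataset$meds$patient_id %in% cohort$patient_id, ]
  first <- m |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_med = min(.data$date), .groups = "drop")
  x <- dplyr::inner_join(cohort, first, by = "patient_id")
  n_members <- cohort |> dplyr::count(.data$site_id, name = "n_members")
  if (nrow(x) == 0) return(check_result())
  x$delta <- as.numeric(x$first_med - x$ced)
  summ <- x |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(q1 = stats::quantile(.data$delta, 0.25, names = FALSE),
                     median = stats::quantile(.data$delta, 0.5, names = FALSE),
                     q3 = stats::quantile(.data$delta, 0.75, names = FALSE),
                     frac_negative = mean(.data$delta < 0),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(n_members, by = "site_id")
  long <- tidyr::pivot_longer(summ, c("q1", "median", "q3", "frac_negative"),
                              names_to = "stratum", values_to = "value")
  dplyr::bind_rows(
    check_result(long$site_id, long$stratum, long$value, long$n),
    check_result(summ$site_id, "n_with_med", summ$n, summ$n_members)) |>
    dplyr::arrange(.data$site_id, .data$stratum)
}

#' Per-site geocode granularity proportions
#'
#' Proportions over the five geocode levels; they sum to one per site.
#'
#' @param dataset A `dq_dataset`.
#' @return Check-result tibble (stratum = geocode level).
#' @export
geocode_granularity <- function(dataset) {
  levels <- cdm_value_sets()$geocode_level
  p <- dataset$patients
  grid <- tidyr::expand_grid(site_id = sort(unique(p$site_id)),
                             stratum = levels)
  n <- p |>
    dplyr::count(.data$site_id, .data$geocode_level, name = "k") |>
    dplyr::rename(stratum = "geocode_level")
  tot <- p |> dplyr::count(.data$site_id, name = "n")
  out <- grid |>
    dplyr::left_join(n, by = c("site_id", "stratum")) |>
    dplyr::left_join(tot, by = "site_id")
  out$k[is.na(out$k)] <- 0L
  check_result(out$site_id, out$stratum, out$k / out$n, out$n)
}

#' Per-site summary of a quantitative variable's distribution
#'
#' Quartiles (type 7), mean, the largest fraction of records sharing one
#' exact value (`top_mass`), and the fraction outside the configured
#' physiologic bounds (`out_of_range`; zero when no bounds are configured
#' for the variable).
#'
#' @inheritParams completeness_trend
#' @return Check-result tibble with strata `q1`, `median`, `q3`, `mean`,
#'   `top_mass`, `out_of_range` (denominator = record count).
#' @export
value_distribution <- function(dataset, variable,
                               config = analysis_config(), records = NULL) {
  r <- if (is.null(records)) select_records(dataset, variable) else records
  r <- r[!is.na(r$value), ]
  if (nrow(r) == 0) return(check_result())
  bounds <- config$schema$bounds[[variable]]
  out <- r |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      q1 = stats::quantile(.data$value, 0.25, names = FALSE),
      median = stats::quantile(.data$value, 0.5, names = FALSE),
      q3 = stats::quantile(.data$value, 0.75, names = FALSE),
      mean = mean(.data$value),
      top_mass = max(table(.data$value)) / dplyr::n(),
      out_of_range = if (is.null(bounds)) 0
        else mean(.data$value < bounds[1] | .data$value > bounds[2]),
      denominator = dplyr::n(), .groups = "drop")
  long <- tidyr::pivot_longer(out, c("q1", "median", "q3", "mean",
                                     "top_mass", "out_of_range"),
                              names_to = "stratum", values_to = "value")
  check_result(long$site_id, long$stratum, long$value, long$denominator) |>
    dplyr::arrange(.data$site_id, .data$stratum)
}

#' Per-site per-year record counts
#'
#' Years within the site's data span with no records are reported as explicit
#' zeros, so spike detection sees the full series.
#'
#' @inheritParams completeness_trend
#' @return Check-result tibble (stratum = year, value = count, denominator =
#'   the site's total record count for the variable).
#' @export
yearly_count_trend <- function(dataset, variable,
                               config = analysis_config()) {
  r <- select_records(dataset, variable)
  grid <- site_years(dataset)
  n <- tibble::tibble(site_id = r$site_id, year = year_of(r$date)) |>
    dplyr::count(.data$site_id, .data$year, name = "k")
  tot <- r |> dplyr::count(.data$site_id, name = "total")
  out <- grid |>
    dplyr::left_join(n, by = c("site_id", "year")) |>
    dplyr::left_join(tot, by = "site_id")
  out$k[is.na(out$k)] <- 0L
  out$total[is.na(out$total)] <- 0L
  check_result(out$site_id, out$year, out$k, out$total)
}

#' Records per patient for a variable
#'
#' Per site, the number of records divided by the number of patients with at
#' least one record; the surface for duplicate-extraction detection.
#'
#' @inheritParams completeness_trend
#' @return Check-result tibble (stratum `"all"`, denominator = patients with
#'   a record).
#' @export
per_patient_density <- function(dataset, variable,
                                config = analysis_config(), records = NULL) {
  r <- if (is.null(records)) select_records(dataset, variable) else records
  if (nrow(r) == 0) return(check_result())
  out <- r |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(n_rec = dplyr::n(),
                     n_pat = dplyr::n_distinct(.data$patient_id),
                     .groups = "drop")
  check_result(out$site_id, "all", out$n_rec / out$n_pat, out$n_pat)
}

#' Per-site frequency distribution of a categorical field
#'
#' @inheritParams completeness_trend
#' @return Check-result tibble (stratum = category, value = proportion).
#' @export
category_frequency <- function(dataset, variable,
                               config = analysis_config()) {
  field <- switch(variable,
    meds = list(dataset$meds, "drug_class"),
    procs = list(dataset$procs, "code_group"),
    "visit:visit_type" = list(dataset$visits, "visit_type"),
    "visit:provider_specialty" = list(dataset$visits, "provider_specialty"),
    "patient:geocode_level" = list(dataset$patients, "geocode_level"),
    "patient:ethnicity" = list(dataset$patients, "ethnicity"),
    stop(sprintf("no categorical selector for variable: %s", variable),
         call. = FALSE))
  tab <- field[[1]]; col <- field[[2]]
  if (nrow(tab) == 0) return(check_result())
  out <- tab |>
    dplyr::count(.data$site_id, .data[[col]], name = "k") |>
    dplyr::group_by(.data$site_id) |>
    dplyr::mutate(n = sum(.data$k)) |>
    dplyr::ungroup()
  check_result(out$site_id, out[[col]], out$k / out$n, out$n)
}

#' Attrition funnel as check results
#'
#' @param attrition Result of [apply_attrition()].
#' @return Check-result tibble (stratum = `step_00`..`step_10`, value =
#'   retained, denominator = retained at step 0).
#' @export
attrition_results <- function(attrition) {
  rep <- attrition$report
  base <- rep[rep$step == 0, c("site_id", "retained")]
  names(base)[2] <- "base"
  out <- dplyr::left_join(rep, base, by = "site_id")
  check_result(out$site_id, sprintf("step_%02d", out$step), out$retained,
               out$base)
}

conformance_results <- function(dataset, domain, schema) {
  f <- validate_conformance(dataset, schema)
  f <- f[f$domain == domain, ]
  tot <- nrow(dataset[[domain]])
  check_result(f$site_id, paste0(f$field, "|", f$dq_issue), f$count,
               rep(tot, nrow(f)))
}

#' Execute a catalog round over a dataset
#'
#' DQ1 mode computes each site's results from that site's records in
#' isolation (aggregate-only contract: outputs never carry patient
#' identifiers); DQ2 mode computes from pooled rows. Catalog entries bound to
#' the `unbound` executor (domains outside the simplified data model) are
#' skipped with a message.
#'
#' @param dataset A `dq_dataset`.
#' @param round `"DQ1"` or `"DQ2"`.
#' @param config An [analysis_config()].
#' @param catalog Catalog tibble; defaults to [load_catalog()] for the round.
#' @param quiet Suppress per-check messages.
#' @return List with `results` (check-result tibble with `check_num`),
#'   `attrition`, `cohort`, `egfr` and `conformance`.
#' @export
run_round <- function(dataset, round = c("DQ1", "DQ2"),
                      config = analysis_config(), catalog = NULL,
                      quiet = TRUE) {
  round <- match.arg(round)
  if (is.null(catalog)) catalog <- load_catalog(round)
  if (round == "DQ1") {
    sites <- sort(unique(dataset$patients$site_id))
    parts <- lapply(sites, function(s)
      run_round_pooled(subset_site(dataset, s), catalog, config, quiet))
    results <- dplyr::bind_rows(lapply(parts, `[[`, "results"))
    attr_rep <- dplyr::bind_rows(lapply(parts, function(p) p$attrition$report))
    cohort <- dplyr::bind_rows(lapply(parts, function(p) p$attrition$cohort))
    egfr <- dplyr::bind_rows(lapply(parts, function(p) p$attrition$egfr))
    conf <- dplyr::bind_rows(lapply(parts, `[[`, "conformance"))
    attrition <- list(report = dplyr::arrange(attr_rep, .data$site_id,
                                              .data$step),
                      cohort = cohort)
  } else {
    part <- run_round_pooled(dataset, catalog, config, quiet)
    results <- part$results
    attrition <- list(report = part$attrition$report,
                      cohort = part$attrition$cohort)
    egfr <- part$attrition$egfr
    conf <- part$conformance
  }
  # coordinating-center step: pooled prevalence filter for code matrices
  cu_checks <- catalog$check_num[catalog$executor == "code_utilization"]
  if (length(cu_checks) > 0 && nrow(results) > 0) {
    finalized <- lapply(cu_checks, function(cn) {
      finalize_code_utilization(results[results$check_num == cn, ], config)
    })
    results <- dplyr::bind_rows(
      results[!(results$check_num %in% cu_checks), ],
      dplyr::bind_rows(finalized))
  }
  list(results = dplyr::arrange(results, .data$check_num, .data$site_id,
                                .data$stratum),
       attrition = attrition$report, cohort = attrition$cohort,
       egfr = egfr, conformance = conf, round = round, catalog = catalog)
}

run_round_pooled <- function(dataset, catalog, config, quiet) {
  attrition <- apply_attrition(dataset, config)
  conf <- validate_conformance(dataset, config$schema)
  out <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    ex <- catalog$executor[i]; v <- catalog$variable[i]
    res <- switch(ex,
      completeness_trend = completeness_trend(dataset, v, config),
      same_day_concordance = same_day_concordance(dataset, config),
      pair_correlation = pair_correlation(dataset, config),
      unit_mapped_proportion =
        unit_mapped_proportion(dataset, sub("^lab:", "", v)),
      code_utilization = code_utilization_raw(dataset, attrition$cohort,
                                              sub("^proc:", "", v)),
      med_timing = med_timing(dataset, attrition$cohort, config),
      geocode_granularity = geocode_granularity(dataset),
      value_distribution = {
        rec <- if (v == "derived:egfr") {
          e <- attrition$egfr
          tibble::tibble(site_id = e$site_id, value = e$egfr)
        } else NULL
        value_distribution(dataset, v, config, records = rec)
      },
      attrition_funnel = attrition_results(attrition),
      egfr_threshold_curve = {
        r <- egfr_threshold_curve(attrition$cohort, attrition$egfr)
        check_result(r$site_id, r$threshold, r$proportion, r$n_members)
      },
      egfr_trajectory_medians = {
        r <- egfr_trajectory_medians(attrition$cohort, attrition$egfr)
        check_result(r$site_id, r$offset, r$median_egfr, r$n)
      },
      yearly_count_trend = yearly_count_trend(dataset, v, config),
      per_patient_density = {
        rec <- if (v == "derived:egfr") {
          e <- attrition$egfr
          tibble::tibble(site_id = e$site_id, patient_id = e$patient_id)
        } else NULL
        per_patient_density(dataset, v, config, records = rec)
      },
      category_frequency = category_frequency(dataset, v, config),
      conformance_value_sets =
        conformance_results(dataset, catalog_conf_domain(v), config$schema),
      unbound = {
        if (!quiet)
          message(sprintf("check %s: no executor for this data model; skipped",
                          catalog$check_num[i]))
        NULL
      })
    if (!is.null(res) && nrow(res) > 0) {
      res$check_num <- catalog$check_num[i]
      out[[i]] <- res[, c("check_num", "site_id", "stratum", "value",
                          "denominator")]
    }
  }
  list(results = dplyr::bind_rows(out), attrition = attrition,
       conformance = conf)
}

catalog_conf_domain <- function(variable) {
  switch(variable, vitals = "vitals", labs = "labs", meds = "meds",
         procs = "procs", patients = "patients", "patients")
}
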