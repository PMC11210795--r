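# Pediatric eGFR (bedside Schwartz), creatinine-height linkage, and the
# eleven-step sequential cohort attrition pipeline.

ATTRITION_LABELS <- c(
  "any encounter in study interval",
  "any in-person visit in study interval",
  "at least one serum creatinine",
  "age 1-18 years at serum creatinine",
  "height within 90 days of eligible creatinine",
  "at least one eGFR in [30, 90)",
  "two additional eGFRs in range, >= 90 days after the first",
  "no intervening normal (>=90) eGFR",
  "in-person nephrology visit",
  "no chronic dialysis before cohort entry",
  "no kidney transplant before cohort entry")

#' Pediatric eGFR by the bedside Schwartz equation
#'
#' eGFR = k * height(cm) / SCr(mg/dL), with k = 0.413 by default, in
#' mL/min/1.73m2. Vectorized.
#'
#' @param scr Serum creatinine, mg/dL (> 0).
#' @param height Height, cm (> 0).
#' @param k Schwartz constant.
#' @return eGFR in mL/min/1.73m2.
#' @export
compute_egfr <- function(scr, height, k = 0.413) {
  if (any(!is.finite(scr)) || any(scr <= 0))
    stop("implausible record: serum creatinine must be positive", call. = FALSE)
  if (any(!is.finite(height)) || any(height <= 0))
    stop("implausible record: height must be positive", call. = FALSE)
  k * height / scr
}

age_years <- function(date, birth_date) {
  as.numeric(date - birth_date) / 365.25
}

# Vectorized creatinine-height linkage over many patients.
# scr: tibble (patient_id, site_id, date, value, birth_date) already
# age-filtered and positive; heights: tibble (patient_id, date, value).
# Heights are deduplicated to one per patient-day (smallest value); the
# nearest height within the window wins, earlier date on a tie.
link_height_all <- function(scr, heights, config) {
  empty <- tibble::tibble(patient_id = character(), site_id = character(),
                          date = as.Date(character()), egfr = numeric(),
                          scr = numeric(), height_used = numeric(),
                          height_date = as.Date(character()))
  if (nrow(scr) == 0 || nrow(heights) == 0) return(empty)
  heights <- heights[is.finite(heights$value) & heights$value > 0, ]
  if (nrow(heights) == 0) return(empty)
  h <- heights |>
    dplyr::group_by(.data$patient_id, .data$date) |>
    dplyr::summarise(value = min(.data$value), .groups = "drop")

  pid_levels <- sort(unique(c(scr$patient_id, h$patient_id)))
  K <- 1e6 # > any day number; keys are patient-major
  hkey <- match(h$patient_id, pid_levels) * K + as.numeric(h$date)
  ord <- order(hkey)
  h <- h[ord, ]; hkey <- hkey[ord]
  hpid <- match(h$patient_id, pid_levels)
  hday <- as.numeric(h$date)

  spid <- match(scr$patient_id, pid_levels)
  sday <- as.numeric(scr$date)
  skey <- spid * K + sday

  ilo <- findInterval(skey, hkey)
  lo_ok <- ilo >= 1 & ilo <= length(hkey) & hpid[pmax(ilo, 1)] == spid
  ihi <- ilo + 1
  hi_ok <- ihi <= length(hkey) & hpid[pmin(ihi, length(hkey))] == spid
  d_lo <- ifelse(lo_ok, sday - hday[pmax(ilo, 1)], Inf)
  d_hi <- ifelse(hi_ok, hday[pmin(ihi, length(hkey))] - sday, Inf)
  # nearest wins; exact tie goes to the earlier (lower-date) height
  use_lo <- d_lo <= d_hi
  idx <- ifelse(use_lo, ilo, ihi)
  dist <- pmin(d_lo, d_hi)
  keep <- is.finite(dist) & dist <= config$height_window_days
  if (!any(keep)) return(empty)
  scr <- scr[keep, ]; idx <- idx[keep]
  tibble::tibble(
    patient_id = scr$patient_id,
    site_id = scr$site_id,
    date = scr$date,
    egfr = compute_egfr(scr$value, h$value[idx], config$schwartz_k),
    scr = scr$value,
    height_used = h$value[idx],
    height_date = h$date[idx])
}

#' Pair one patient's serum creatinines with heights and compute eGFR
#'
#' Each age-eligible serum creatinine is paired with the nearest-in-time
#' height within the configured window (ties broken toward the earlier
#' height); creatinines with no eligible height yield no result.
#'
#' @param labs Tibble of the patient's lab records (needs `lab`, `date`,
#'   `value`).
#' @param heights Tibble of the patient's height measurements (`date`,
#'   `value`).
#' @param birth_date The patient's birth date.
#' @param config An [analysis_config()].
#' @return Tibble with one row per computed eGFR (`date`, `egfr`, `scr`,
#'   `height_used`, `height_date`).
#' @export
link_height <- function(labs, heights, birth_date, config = analysis_config()) {
  scr <- labs[labs$lab == "serum_creatinine" & !is.na(labs$value) &
                labs$value > 0, , drop = FALSE]
  scr <- tibble::as_tibble(scr)
  scr$date <- as.Date(scr$date)
  age <- age_years(scr$date, as.Date(birth_date))
  scr <- scr[age >= config$age_min & age <= config$age_max, , drop = FALSE]
  scr$patient_id <- "p"; scr$site_id <- "s"
  h <- tibble::tibble(patient_id = "p", date = as.Date(heights$date),
                      value = heights$value)
  out <- link_height_all(scr[, c("patient_id", "site_id", "date", "value")],
                         h, config)
  out[, c("date", "egfr", "scr", "height_used", "height_date")]
}

#' eGFR results for every patient in a dataset
#'
#' Age-eligible serum creatinines paired with heights per [link_height()],
#' across all patients.
#'
#' @param dataset A `dq_dataset`.
#' @param config An [analysis_config()].
#' @return Tibble (`patient_id`, `site_id`, `date`, `egfr`, `scr`,
#'   `height_used`, `height_date`).
#' @export
compute_egfr_table <- function(dataset, config = analysis_config()) {
  labs <- dataset$labs
  scr <- labs[labs$lab == "serum_creatinine" & !is.na(labs$value) &
                labs$value > 0, , drop = FALSE]
  scr <- dplyr::left_join(scr,
                          dataset$patients[, c("patient_id", "birth_date")],
                          by = "patient_id")
  age <- age_years(scr$date, scr$birth_date)
  scr <- scr[age >= config$age_min & age <= config$age_max, , drop = FALSE]
  heights <- dataset$vitals[dataset$vitals$measure == "height", , drop = FALSE]
  link_height_all(scr[, c("patient_id", "site_id", "date", "value")],
                  heights[, c("patient_id", "date", "value")], config)
}

# Earliest qualifying anchor for one patient.
# low_days / normal_days: sorted integer day numbers of in-range and
# normal-range eGFRs. Returns list(step6, step7, ced_day).
qualifying_anchor <- function(low_days, normal_days, gap_days) {
  step6 <- FALSE; step7 <- FALSE; ced <- NA_real_
  if (length(low_days) < 3) return(list(step6 = step6, step7 = step7, ced = ced))
  for (f in low_days) {
    addl <- low_days[low_days >= f + gap_days]
    if (length(addl) >= 2) {
      step6 <- TRUE
      if (length(normal_days) > 0) {
        # normals strictly between the anchor and each additional eGFR
        n_through_f <- findInterval(f, normal_days)
        n_before_a <- findInterval(addl - 1, normal_days)
        addl <- addl[(n_before_a - n_through_f) == 0]
      }
      if (length(addl) >= 2) { step7 <- TRUE; ced <- f; break }
    }
  }
  list(step6 = step6, step7 = step7, ced = ced)
}

#' Apply the eleven-step cohort attrition pipeline
#'
#' Steps are applied strictly in order; a patient counted at step k satisfies
#' steps 0..k. Cohort entry date (CED) is the date of the first eGFR of the
#' earliest sequence satisfying the qualifying-eGFR steps. Step counts are
#' non-increasing within every site by construction.
#'
#' @param dataset A `dq_dataset`.
#' @param config An [analysis_config()].
#' @return List with `report` (tibble: `site_id`, `step`, `label`,
#'   `retained`), `cohort` (tibble: `patient_id`, `site_id`, `ced`) and
#'   `egfr` (the [compute_egfr_table()] result).
#' @export
apply_attrition <- function(dataset, config = analysis_config()) {
  p <- dataset$patients
  interval <- config$study_interval
  v <- dataset$visits
  vy <- year_of(v$date)
  in_int <- !is.na(vy) & vy >= interval[1] & vy <= interval[2]

  s0_ids <- unique(v$patient_id[in_int])
  s1_ids <- unique(v$patient_id[in_int & v$in_person %in% TRUE])

  labs <- dataset$labs
  scr <- labs[labs$lab == "serum_creatinine", , drop = FALSE]
  s2_ids <- unique(scr$patient_id)

  scr_b <- dplyr::left_join(scr, p[, c("patient_id", "birth_date")],
                            by = "patient_id")
  age <- age_years(scr_b$date, scr_b$birth_date)
  s3_ids <- unique(scr_b$patient_id[age >= config$age_min & age <= config$age_max])

  egfr <- compute_egfr_table(dataset, config)
  s4_ids <- unique(egfr$patient_id)

  low <- egfr[egfr$egfr >= config$egfr_low & egfr$egfr < config$egfr_high, ]
  s5_ids <- unique(low$patient_id)

  # steps 6-7: earliest qualifying anchor per patient
  norm <- egfr[egfr$egfr >= config$egfr_high, ]
  low_split <- split(as.numeric(low$date), low$patient_id)
  norm_split <- split(as.numeric(norm$date), norm$patient_id)
  anchors <- lapply(names(low_split), function(pid) {
    qualifying_anchor(sort(unique(low_split[[pid]])),
                      sort(unique(norm_split[[pid]])), config$gap_days)
  })
  names(anchors) <- names(low_split)
  s6_ids <- names(anchors)[vapply(anchors, `[[`, TRUE, "step6")]
  s7_ids <- names(anchors)[vapply(anchors, `[[`, TRUE, "step7")]
  ced <- vapply(anchors, `[[`, numeric(1), "ced")
  ced <- ced[!is.na(ced)]

  s8_ids <- unique(v$patient_id[v$in_person %in% TRUE &
                                  v$provider_specialty %in% "nephrology"])

  pr <- dataset$procs
  excl_before_ced <- function(group) {
    px <- pr[pr$code_group == group, , drop = FALSE]
    px <- px[px$patient_id %in% names(ced), , drop = FALSE]
    unique(px$patient_id[as.numeric(px$date) < ced[px$patient_id]])
  }
  dial_excl <- excl_before_ced("chronic_dialysis")
  tx_excl <- excl_before_ced("kidney_transplant")

  surv <- p$patient_id
  step_sets <- list(s0_ids, s1_ids, s2_ids, s3_ids, s4_ids, s5_ids,
                    s6_ids, s7_ids, s8_ids)
  retained <- vector("list", 11)
  for (k in seq_along(step_sets)) {
    surv <- surv[surv %in% step_sets[[k]]]
    retained[[k]] <- surv
  }
  surv <- surv[!(surv %in% dial_excl)]
  retained[[10]] <- surv
  surv <- surv[!(surv %in% tx_excl)]
  retained[[11]] <- surv

  site_of <- stats::setNames(p$site_id, p$patient_id)
  all_sites <- sort(unique(p$site_id))
  report <- dplyr::bind_rows(lapply(0:10, function(k) {
    ids <- retained[[k + 1]]
    counts <- table(factor(site_of[ids], levels = all_sites))
    tibble::tibble(site_id = all_sites, step = k,
                   label = ATTRITION_LABELS[k + 1],
                   retained = as.integer(counts))
  })) |>
    dplyr::arrange(.data$site_id, .data$step)

  members <- retained[[11]]
  cohort <- tibble::tibble(
    patient_id = members,
    site_id = unname(site_of[members]),
    ced = as.Date(unname(ced[members]), origin = "1970-01-01")) |>
    dplyr::arrange(.data$site_id, .data$patient_id)

  list(report = report, cohort = cohort, egfr = egfr)
}

#' Proportion of cohort with at least one eGFR below each threshold
#'
#' For each site and threshold t, the fraction of cohort members with >= 1
#' eGFR < t; non-decreasing in t within a site.
#'
#' @param cohort Cohort tibble from [apply_attrition()].
#' @param egfr eGFR table from [compute_egfr_table()].
#' @param thresholds Numeric thresholds (mL/min/1.73m2).
#' @return Tibble (`site_id`, `threshold`, `proportion`, `n_members`).
#' @export
egfr_threshold_curve <- function(cohort, egfr,
                                 thresholds = seq(30, 90, by = 10)) {
  if (nrow(cohort) == 0)
    return(tibble::tibble(site_id = character(), threshold = numeric(),
                          proportion = numeric(), n_members = integer()))
  min_e <- egfr |>
    dplyr::filter(.data$patient_id %in% cohort$patient_id) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(min_egfr = min(.data$egfr), .groups = "drop")
  members <- dplyr::left_join(cohort, min_e, by = "patient_id")
  dplyr::bind_rows(lapply(thresholds, function(t) {
    members |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(threshold = t,
                       proportion = mean(.data$min_egfr < t, na.rm = TRUE),
                       n_members = dplyr::n(), .groups = "drop")
  })) |>
    dplyr::arrange(.data$site_id, .data$threshold)
}

#' Median eGFR by integer year offset from cohort entry
#'
#' Offsets are `floor((date - CED)/365.25)`; medians per site per offset.
#'
#' @param cohort Cohort tibble with `ced`.
#' @param egfr eGFR table.
#' @return Tibble (`site_id`, `offset`, `median_egfr`, `n`).
#' @export
egfr_trajectory_medians <- function(cohort, egfr) {
  x <- dplyr::inner_join(egfr, cohort[, c("patient_id", "ced")],
                         by = "patient_id")
  if (nrow(x) == 0)
    return(tibble::tibble(site_id = character(), offset = integer(),
                          median_egfr = numeric(), n = integer()))
  x$offset <- as.integer(floor(as.numeric(x$date - x$ced) / 365.25))
  x |>
    dplyr::group_by(.data$site_id, .data$offset) |>
    dplyr::summarise(median_egfr = stats::median(.data$egfr),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$site_id, .data$offset)
}
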