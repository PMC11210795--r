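# Injectable data-quality faults with a ground-truth plant registry.
# Each anomaly kind has a default magnitude chosen so that detection at the
# default thresholds is unambiguous; all magnitudes are overridable.

ANOMALY_KINDS <- c("drop_specialty", "duplicate_vitals", "height_unit_error",
                   "default_9999_labs", "qualitative_urine_protein_masses",
                   "missing_lab_year", "volume_spike_year",
                   "pre_entry_med_spike", "geocode_downgrade",
                   "ethnicity_mapping_error", "late_data_onset")

#' Specify an anomaly to inject
#'
#' @param kind One of the supported anomaly kinds (see Details).
#' @param site_id Target site.
#' @param ... Kind-specific parameters (e.g. `fraction`, `year`,
#'   `mass_points`); unset parameters take the kind's default.
#' @details Supported kinds: `drop_specialty`, `duplicate_vitals`,
#'   `height_unit_error`, `default_9999_labs`,
#'   `qualitative_urine_protein_masses`, `missing_lab_year`,
#'   `volume_spike_year`, `pre_entry_med_spike`, `geocode_downgrade`,
#'   `ethnicity_mapping_error`, `late_data_onset`.
#' @return A list of class `anomaly_spec`.
#' @export
anomaly_spec <- function(kind, site_id, ...) {
  kind <- match.arg(kind, ANOMALY_KINDS)
  params <- list(...)
  if (!is.null(params$fraction))
    stopifnot(params$fraction > 0, params$fraction <= 1)
  structure(list(kind = kind, site_id = site_id, params = params),
            class = "anomaly_spec")
}

default_params <- function(kind) {
  switch(kind,
    drop_specialty = list(fraction = 1.0),
    duplicate_vitals = list(measure = "height", fraction = 1.0),
    height_unit_error = list(fraction = 0.3),
    default_9999_labs = list(lab = "urine_protein_quant", fraction = 0.2,
                             value = 9999),
    qualitative_urine_protein_masses = list(mass_points = c(60, 100, 150),
                                            fraction = 0.5),
    missing_lab_year = list(lab = "serum_creatinine", year = 2014),
    volume_spike_year = list(year = 2017, factor = 3),
    pre_entry_med_spike = list(window_days = c(7, 60), fraction = 0.9),
    geocode_downgrade = list(fraction = 0.8, to = "zip5"),
    ethnicity_mapping_error = list(fraction = 1.0, bad_code = "H"),
    late_data_onset = list(cutoff_year = 2015))
}

expected_signature <- function(kind, params) {
  switch(kind,
    drop_specialty = c("missingness", "specialty:nephrology"),
    duplicate_vitals = c("high counts",
                         paste0("vital:", params$measure)),
    height_unit_error = c("outlier values", "vital:height"),
    default_9999_labs = c("outlier values", paste0("lab:", params$lab)),
    qualitative_urine_protein_masses =
      c("atypical numeric distribution", "lab:urine_protein_quant"),
    missing_lab_year = c("missingness", paste0("lab:", params$lab)),
    volume_spike_year = c("high spike", "visit:any"),
    pre_entry_med_spike = c("outlier values", "med:antihypertensive"),
    geocode_downgrade = c("atypical code distribution",
                          "patient:geocode_level"),
    ethnicity_mapping_error = c("mapping error", "patient:ethnicity"),
    late_data_onset = c("missingness", "cohort_entry"))
}

#' Inject one anomaly into a dataset
#'
#' Only the targeted site/domain is modified. Returns both the modified
#' dataset and the plant-registry entry carrying the expected detection
#' signature (data-quality issue code and data element).
#'
#' @param dataset A `dq_dataset`.
#' @param spec An [anomaly_spec()].
#' @param seed Seed for the anomaly's own randomness.
#' @param config An [analysis_config()] (used by anomalies that need the
#'   cohort, e.g. `pre_entry_med_spike`).
#' @return List with `dataset` and `registry` (one-row tibble: `site_id`,
#'   `kind`, `params_json`, `expected_dq_issue`, `expected_element`).
#' @export
inject_anomaly <- function(dataset, spec, seed = 1L,
                           config = analysis_config()) {
  if (!inherits(spec, "anomaly_spec")) stop("spec must be an anomaly_spec")
  if (!spec$site_id %in% dataset$patients$site_id)
    stop(sprintf("unknown site: %s", spec$site_id), call. = FALSE)
  params <- utils::modifyList(default_params(spec$kind), spec$params)
  set.seed(seed)
  s <- spec$site_id
  ds <- dataset

  pick <- function(idx, fraction) {
    if (fraction >= 1) idx
    else idx[stats::runif(length(idx)) < fraction]
  }

  switch(spec$kind,
    drop_specialty = {
      i <- which(ds$visits$site_id == s &
                   ds$visits$provider_specialty == "nephrology")
      ds$visits$provider_specialty[pick(i, params$fraction)] <- "none"
    },
    duplicate_vitals = {
      i <- which(ds$vitals$site_id == s & ds$vitals$measure == params$measure)
      ds$vitals <- dplyr::bind_rows(ds$vitals,
                                    ds$vitals[pick(i, params$fraction), ])
    },
    height_unit_error = {
      i <- pick(which(ds$vitals$site_id == s & ds$vitals$measure == "height"),
                params$fraction)
      ds$vitals$value[i] <- ds$vitals$value[i] / 2.54
    },
    default_9999_labs = {
      i <- pick(which(ds$labs$site_id == s & ds$labs$lab == params$lab),
                params$fraction)
      ds$labs$value[i] <- params$value
    },
    qualitative_urine_protein_masses = {
      i <- pick(which(ds$labs$site_id == s &
                        ds$labs$lab == "urine_protein_quant"),
                params$fraction)
      ds$labs$value[i] <- sample(params$mass_points, length(i), replace = TRUE)
    },
    missing_lab_year = {
      drop <- ds$labs$site_id == s & ds$labs$lab == params$lab &
        year_of(ds$labs$date) == params$year
      ds$labs <- ds$labs[!drop, ]
    },
    volume_spike_year = {
      i <- which(ds$visits$site_id == s &
                   year_of(ds$visits$date) == params$year)
      extra <- ds$visits[rep(i, params$factor - 1), ]
      extra$visit_id <- sprintf("%s-dup%06d", extra$visit_id,
                                seq_len(nrow(extra)))
      ds$visits <- dplyr::bind_rows(ds$visits, extra)
    },
    pre_entry_med_spike = {
      site_ds <- subset_site(ds, s)
      coh <- apply_attrition(site_ds, config)$cohort
      ah <- setdiff(unique(cdm_value_sets()$drug_class), "other")
      med_members <- coh[coh$patient_id %in%
                           ds$meds$patient_id[ds$meds$drug_class %in% ah], ]
      affected <- med_members[pick(seq_len(nrow(med_members)),
                                   params$fraction), ]
      if (nrow(affected) > 0) {
        lag <- round(stats::runif(nrow(affected), params$window_days[1],
                                  params$window_days[2]))
        new_first <- stats::setNames(affected$ced - lag, affected$patient_id)
        m <- ds$meds
        for (pid in affected$patient_id) {
          j <- which(m$patient_id == pid & m$drug_class %in% ah)
          jf <- j[which.min(as.numeric(m$date[j]))]
          m$date[jf] <- new_first[[pid]]
          # no earlier fills remain before the moved start
          drop <- j[as.numeric(m$date[j]) < as.numeric(new_first[[pid]])]
          if (length(drop) > 0) m <- m[-drop, ]
        }
        ds$meds <- m
      }
    },
    geocode_downgrade = {
      i <- pick(which(ds$patients$site_id == s &
                        ds$patients$geocode_level == "block_group"),
                params$fraction)
      ds$patients$geocode_level[i] <- params$to
    },
    ethnicity_mapping_error = {
      i <- pick(which(ds$patients$site_id == s &
                        ds$patients$ethnicity == "hispanic"),
                params$fraction)
      ds$patients$ethnicity[i] <- params$bad_code
    },
    late_data_onset = {
      cut <- as.Date(sprintf("%d-01-01", params$cutoff_year))
      for (d in c("visits", "vitals", "labs", "meds", "procs")) {
        drop <- ds[[d]]$site_id == s & ds[[d]]$date < cut
        ds[[d]] <- ds[[d]][!drop, ]
      }
      # the site's data span starts at the cutoff now
      i <- which(ds$site_span$site_id == s)
      v <- ds$visits[ds$visits$site_id == s, ]
      ds$site_span$first_year[i] <- if (nrow(v) > 0)
        min(year_of(v$date)) else NA_integer_
    })

  sig <- expected_signature(spec$kind, params)
  registry <- tibble::tibble(
    site_id = s, kind = spec$kind,
    params_json = as.character(yaml::as.yaml(params)),
    expected_dq_issue = sig[1], expected_element = sig[2])
  list(dataset = ds, registry = registry)
}

#' Inject a set of anomalies and collect the plant registry
#'
#' @param dataset A `dq_dataset`.
#' @param specs List of [anomaly_spec()]s.
#' @param seed Base seed; plant i uses `seed + i`.
#' @param config An [analysis_config()].
#' @return List with `dataset` and `registry` (one row per plant).
#' @export
inject_anomalies <- function(dataset, specs, seed = 1L,
                             config = analysis_config()) {
  reg <- list()
  for (i in seq_along(specs)) {
    out <- inject_anomaly(dataset, specs[[i]], seed = seed + i,
                          config = config)
    dataset <- out$dataset
    reg[[i]] <- out$registry
  }
  list(dataset = dataset, registry = dplyr::bind_rows(reg))
}

#' Expected issues implied by a plant registry
#'
#' One expected-issue row per plant, with the site, element and data-quality
#' issue code the detection pipeline is expected to emit.
#'
#' @param registry Registry tibble from [inject_anomaly()].
#' @return Tibble (`site_id`, `element`, `dq_issue`).
#' @export
plant_expectations <- function(registry) {
  if (is.null(registry) || nrow(registry) == 0)
    return(tibble::tibble(site_id = character(), element = character(),
                          dq_issue = character()))
  tibble::tibble(site_id = registry$site_id,
                 element = registry$expected_element,
                 dq_issue = registry$expected_dq_issue)
}

#' The default one-plant-per-kind anomaly battery
#'
#' One plant of each anomaly kind at default magnitude, each at a distinct
#' site (the first 11 sites in sort order).
#'
#' @param dataset A `dq_dataset` with at least 11 sites.
#' @return List of [anomaly_spec()]s.
#' @export
default_plants <- function(dataset) {
  sites <- sort(unique(dataset$patients$site_id))
  if (length(sites) < length(ANOMALY_KINDS))
    stop("need at least 11 sites for the default battery")
  purrr::map2(ANOMALY_KINDS, sites[seq_along(ANOMALY_KINDS)],
              function(k, s) anomaly_spec(k, s))
}

#' Subset a dataset to one site
#'
#' @param dataset A `dq_dataset`.
#' @param site One site id.
#' @return A `dq_dataset` containing only that site's records.
#' @export
subset_site <- function(dataset, site) {
  ds <- dataset
  ds$patients <- ds$patients[ds$patients$site_id == site, ]
  for (d in c("visits", "vitals", "labs", "meds", "procs"))
    ds[[d]] <- ds[[d]][ds[[d]]$site_id == site, ]
  ds$site_span <- ds$site_span[ds$site_span$site_id == site, ]
  ds
}
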