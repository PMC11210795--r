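# The simplified common data model: dataset container, CSV readers/writers
# and structural conformance validation.

DOMAINS <- c("patients", "visits", "vitals", "labs", "meds", "procs")

#' Construct a dataset from domain tables
#'
#' Bundles the six domain tables, derives the per-site data span (first/last
#' calendar year with any visit) and attaches a `site_id` column to every
#' record table by joining through `patients`. Records whose `patient_id` does
#' not appear in `patients` are dropped with a warning; `mapped_unit` is
#' (re)computed from the schema's allowed-unit lists.
#'
#' @param patients,visits,vitals,labs,meds,procs Domain tables (data frames).
#' @param schema Schema configuration, see [default_schema_config()].
#' @return A list of class `dq_dataset` with the six tables plus `site_span`.
#' @export
dq_dataset <- function(patients, visits, vitals, labs, meds, procs,
                       schema = default_schema_config()) {
  patients <- tibble::as_tibble(patients)
  stopifnot(all(c("patient_id", "site_id", "birth_date") %in% names(patients)))
  patients$birth_date <- as.Date(patients$birth_date)
  key <- patients[, c("patient_id", "site_id")]

  link <- function(tab, domain) {
    tab <- tibble::as_tibble(tab)
    tab$site_id <- NULL # always re-derive through patients
    if ("date" %in% names(tab)) tab$date <- as.Date(tab$date)
    bad <- !(tab$patient_id %in% key$patient_id)
    if (any(bad)) {
      warning(sprintf("%s: dropped %d record(s) with unknown patient_id",
                      domain, sum(bad)), call. = FALSE)
      tab <- tab[!bad, , drop = FALSE]
    }
    dplyr::left_join(tab, key, by = "patient_id")
  }

  visits <- link(visits, "visits")
  if ("in_person" %in% names(visits)) visits$in_person <- as.logical(visits$in_person)
  vitals <- link(vitals, "vitals")
  labs   <- link(labs, "labs")
  labs   <- compute_mapped_unit(labs, schema)
  meds   <- link(meds, "meds")
  procs  <- link(procs, "procs")

  vy <- visits |>
    dplyr::mutate(year = year_of(.data$date)) |>
    dplyr::filter(!is.na(.data$year))
  span <- if (nrow(vy) == 0) {
    tibble::tibble(site_id = character(), first_year = integer(),
                   last_year = integer())
  } else {
    vy |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(first_year = min(.data$year),
                       last_year = max(.data$year), .groups = "drop")
  }
  all_sites <- tibble::tibble(site_id = sort(unique(patients$site_id)))
  span <- dplyr::left_join(all_sites, span, by = "site_id")

  structure(list(patients = patients, visits = visits, vitals = vitals,
                 labs = labs, meds = meds, procs = procs, site_span = span),
            class = "dq_dataset")
}

compute_mapped_unit <- function(labs, schema) {
  allowed <- schema$allowed_units
  ok <- mapply(function(lab, unit) {
    !is.na(unit) && unit != "missing" && unit %in% allowed[[lab]]
  }, labs$lab, labs$unit, USE.NAMES = FALSE)
  labs$mapped_unit <- as.logical(ok)
  labs
}

year_of <- function(d) as.integer(format(d, "%Y"))

#' @export
print.dq_dataset <- function(x, ...) {
  cat("<dq_dataset>\n")
  cat(sprintf("  sites: %d   patients: %d\n",
              nrow(x$site_span), nrow(x$patients)))
  for (d in setdiff(DOMAINS, "patients"))
    cat(sprintf("  %-7s %d records\n", d, nrow(x[[d]])))
  invisible(x)
}

#' Load a dataset from a directory of domain CSVs
#'
#' Expects one CSV per domain (`patients.csv`, `visits.csv`, ...). Unknown
#' columns are ignored with a warning; rows whose date fails to parse are
#' rejected with a warning naming the row numbers; records referencing an
#' unknown `patient_id` are dropped with a warning. A missing required file is
#' a fatal error naming the file.
#'
#' @param directory_path Directory containing the six CSVs.
#' @param schema Schema configuration, see [default_schema_config()].
#' @return A `dq_dataset`.
#' @export
load_dataset <- function(directory_path, schema = default_schema_config()) {
  tabs <- lapply(DOMAINS, function(domain) {
    path <- file.path(directory_path, paste0(domain, ".csv"))
    if (!file.exists(path))
      stop(sprintf("required file missing: %s", path), call. = FALSE)
    tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    want <- schema$columns[[domain]]
    extra <- setdiff(names(tab), want)
    if (length(extra) > 0) {
      warning(sprintf("%s.csv: ignoring unknown column(s): %s",
                      domain, paste(extra, collapse = ", ")), call. = FALSE)
      tab <- tab[, intersect(names(tab), want), drop = FALSE]
    }
    missing_cols <- setdiff(want, names(tab))
    if (length(missing_cols) > 0)
      stop(sprintf("%s.csv: missing required column(s): %s",
                   domain, paste(missing_cols, collapse = ", ")), call. = FALSE)
    date_col <- if (domain == "patients") "birth_date" else
      if ("date" %in% want) "date" else NULL
    if (!is.null(date_col)) {
      parsed <- as.Date(tab[[date_col]], format = "%Y-%m-%d")
      bad <- is.na(parsed) & !is.na(tab[[date_col]])
      if (any(bad)) {
        warning(sprintf("%s.csv: rejected %d row(s) with unparseable date (rows: %s)",
                        domain, sum(bad),
                        paste(utils::head(which(bad), 20), collapse = ", ")),
                call. = FALSE)
        tab <- tab[!bad, , drop = FALSE]
        parsed <- parsed[!bad]
      }
      tab[[date_col]] <- parsed
    }
    if ("value" %in% names(tab)) tab$value <- as.numeric(tab$value)
    if ("in_person" %in% names(tab)) tab$in_person <- as.logical(tab$in_person)
    tab
  })
  names(tabs) <- DOMAINS
  dq_dataset(tabs$patients, tabs$visits, tabs$vitals, tabs$labs, tabs$meds,
             tabs$procs, schema = schema)
}

canonical_order <- function(tab, domain) {
  keys <- switch(domain,
    patients = c("site_id", "patient_id"),
    visits   = c("site_id", "patient_id", "date", "visit_id"),
    vitals   = c("site_id", "patient_id", "date", "measure", "value"),
    labs     = c("site_id", "patient_id", "date", "lab", "value"),
    meds     = c("site_id", "patient_id", "date", "drug_class"),
    procs    = c("site_id", "patient_id", "date", "code_group", "code"))
  tab[do.call(order, lapply(keys, function(k) tab[[k]])), , drop = FALSE]
}

#' Write a dataset to a directory of domain CSVs
#'
#' Rows are written in a canonical sort order (site, patient, date,
#' domain-specific key) so repeated writes of the same dataset are
#' byte-identical. The derived `site_id` and `mapped_unit` columns are dropped
#' from non-patient tables; `load_dataset()` re-derives them, giving a
#' round-trip identity.
#'
#' @param dataset A `dq_dataset`.
#' @param directory_path Output directory (created if needed).
#' @export
write_dataset <- function(dataset, directory_path) {
  if (!dir.exists(directory_path)) {
    ok <- dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory: %s", directory_path),
                  call. = FALSE)
  }
  schema_cols <- default_schema_config()$columns
  for (domain in DOMAINS) {
    tab <- canonical_order(dataset[[domain]], domain)
    tab <- tab[, schema_cols[[domain]], drop = FALSE]
    readr::write_csv(tab, file.path(directory_path, paste0(domain, ".csv")),
                     progress = FALSE)
  }
  invisible(directory_path)
}

#' Validate structural conformance of a dataset
#'
#' Checks every coded field against its value set, lab units against the
#' allowed-unit lists, `in_person` against the telehealth/administrative rule,
#' duplicate patient identifiers, and positivity of vital/lab values. Returns
#' one finding per violated invariant with the affected site, domain, field
#' and record count.
#'
#' @param dataset A `dq_dataset`.
#' @param schema Schema configuration.
#' @return Tibble with columns `site_id`, `domain`, `field`, `dq_issue`,
#'   `count` (zero rows when fully conformant).
#' @export
validate_conformance <- function(dataset, schema = default_schema_config()) {
  vs <- schema$value_sets
  findings <- list()
  add <- function(tab, domain, field, codes, issue = "mapping error") {
    bad <- tab[!is.na(tab[[field]]) & !(tab[[field]] %in% codes), , drop = FALSE]
    if (nrow(bad) == 0) return()
    f <- bad |>
      dplyr::count(.data$site_id, name = "count") |>
      dplyr::mutate(domain = domain, field = field, dq_issue = issue)
    findings[[length(findings) + 1]] <<- f
  }
  p <- dataset$patients
  add(p, "patients", "ethnicity", vs$ethnicity)
  add(p, "patients", "geocode_level", vs$geocode_level)
  add(p, "patients", "sex", vs$sex)
  add(dataset$visits, "visits", "visit_type", vs$visit_type)
  add(dataset$vitals, "vitals", "measure", vs$measure)
  add(dataset$vitals, "vitals", "unit", vs$vital_unit)
  add(dataset$labs, "labs", "lab", vs$lab)
  add(dataset$meds, "meds", "drug_class", vs$drug_class)
  add(dataset$procs, "procs", "code_group", vs$code_group)

  # lab unit not in the lab's allowed set (treating "missing" as unmapped)
  unmapped <- dataset$labs[!dataset$labs$mapped_unit, , drop = FALSE]
  if (nrow(unmapped) > 0) {
    findings[[length(findings) + 1]] <- unmapped |>
      dplyr::count(.data$site_id, .data$lab, name = "count") |>
      dplyr::mutate(domain = "labs",
                    field = paste0("unit:", .data$lab),
                    dq_issue = "mapping error") |>
      dplyr::select(-"lab")
  }

  # duplicate patient ids within a site
  dup <- p |>
    dplyr::count(.data$site_id, .data$patient_id, name = "n") |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    findings[[length(findings) + 1]] <- dup |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(count = sum(.data$n), .groups = "drop") |>
      dplyr::mutate(domain = "patients", field = "patient_id",
                    dq_issue = "high counts")
  }

  # telehealth/administrative visits must not be in person, and vice versa
  v <- dataset$visits
  inconsistent <- v[!is.na(v$in_person) &
                      v$in_person == (v$visit_type %in% c("telehealth", "administrative")), ,
                    drop = FALSE]
  if (nrow(inconsistent) > 0) {
    findings[[length(findings) + 1]] <- inconsistent |>
      dplyr::count(.data$site_id, name = "count") |>
      dplyr::mutate(domain = "visits", field = "in_person",
                    dq_issue = "discordant values")
  }

  # non-positive quantitative values
  for (domain in c("vitals", "labs")) {
    tab <- dataset[[domain]]
    bad <- tab[!is.na(tab$value) & tab$value <= 0, , drop = FALSE]
    if (nrow(bad) > 0) {
      findings[[length(findings) + 1]] <- bad |>
        dplyr::count(.data$site_id, name = "count") |>
        dplyr::mutate(domain = domain, field = "value",
                      dq_issue = "outlier values")
    }
  }

  out <- dplyr::bind_rows(findings)
  if (nrow(out) == 0)
    return(tibble::tibble(site_id = character(), domain = character(),
                          field = character(), dq_issue = character(),
                          count = integer()))
  out |>
    dplyr::select("site_id", "domain", "field", "dq_issue", "count") |>
    dplyr::arrange(.data$site_id, .data$domain, .data$field)
}
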