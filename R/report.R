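# Anonymized cross-site report bundles and per-site issue summaries.

#' Build an anonymized report bundle for one round
#'
#' Collects one tidy table per figure family, the issue catalog, and a
#' bijective site alias map ("site 1".."site n"). Raw site identifiers are
#' replaced by aliases everywhere; no patient identifiers appear in any
#' table. A dangling `report_ref` on any issue is a fatal catalog-integrity
#' error.
#'
#' @param round_output Result of [dq_round()] (or [run_round()] plus
#'   [detect_issues()]).
#' @param issues Issue tibble; defaults to `round_output$issues`.
#' @return A list of class `dq_report` with `round`, `alias`, `tables` (named
#'   list of tibbles) and `issues`.
#' @export
build_report <- function(round_output, issues = round_output$issues) {
  results <- round_output$results
  catalog <- round_output$catalog
  ex_of <- stats::setNames(catalog$executor, catalog$check_num)
  sites <- sort(unique(c(results$site_id, round_output$attrition$site_id)))
  alias <- stats::setNames(sprintf("site %d", seq_along(sites)), sites)

  anon <- function(tab) {
    if ("site_id" %in% names(tab)) {
      tab$site <- unname(alias[tab$site_id])
      tab$site_id <- NULL
      tab <- dplyr::relocate(tab, "site")
    }
    tab
  }
  family_table <- function(fams) {
    keep <- results$check_num %in% names(ex_of)[ex_of %in% fams]
    anon(results[keep, ])
  }

  tables <- list(
    fig_attrition = anon(round_output$attrition),
    fig_completeness_trends = family_table("completeness_trend"),
    fig_volume_trends = family_table("yearly_count_trend"),
    fig_code_matrix = family_table("code_utilization"),
    fig_threshold_curves = family_table("egfr_threshold_curve"),
    fig_egfr_trajectory = family_table("egfr_trajectory_medians"),
    fig_distributions = family_table("value_distribution"),
    fig_geocode = family_table("geocode_granularity"),
    fig_med_timing = family_table("med_timing"),
    fig_density = family_table("per_patient_density"),
    fig_bp_correlation = family_table("pair_correlation"),
    fig_bp_concordance = family_table("same_day_concordance"),
    fig_category_frequencies = family_table("category_frequency"),
    tab_unit_mapping = family_table("unit_mapped_proportion"),
    tab_conformance = family_table("conformance_value_sets"))

  if (!is.null(issues) && nrow(issues) > 0) {
    dangling <- setdiff(unique(issues$report_ref), names(tables))
    if (length(dangling) > 0)
      stop(sprintf("issue report_ref does not match any figure table: %s",
                   paste(dangling, collapse = ", ")), call. = FALSE)
  }
  structure(list(round = round_output$round, alias = alias,
                 tables = tables, issues = anon(issues)),
            class = "dq_report")
}

#' @export
print.dq_report <- function(x, ...) {
  cat(sprintf("<dq_report> round %s: %d sites, %d figure tables, %d issues\n",
              x$round, length(x$alias), length(x$tables),
              if (is.null(x$issues)) 0L else nrow(x$issues)))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes every figure table and the issue catalog as CSV (deterministic
#' byte-for-byte given identical inputs) plus rendered figures for the
#' attrition funnel (log scale), the dialysis code-utilization heatmap and
#' the eGFR threshold curves.
#'
#' @param bundle A `dq_report`.
#' @param directory_path Output directory.
#' @param render Render PNG figures (requires a functioning png device).
#' @export
write_report <- function(bundle, directory_path, render = TRUE) {
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$tables))
    readr::write_csv(bundle$tables[[nm]],
                     file.path(directory_path, paste0(nm, ".csv")),
                     progress = FALSE)
  if (!is.null(bundle$issues))
    readr::write_csv(bundle$issues,
                     file.path(directory_path, "issues.csv"),
                     progress = FALSE)
  readr::write_csv(tibble::tibble(alias = unname(bundle$alias)),
                   file.path(directory_path, "site_aliases.csv"),
                   progress = FALSE)
  if (render) {
    att <- bundle$tables$fig_attrition
    if (nrow(att) > 0) {
      g <- ggplot2::ggplot(att, ggplot2::aes(x = factor(.data$step),
                                             y = pmax(.data$retained, 0.5),
                                             fill = .data$site)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::scale_y_log10() +
        ggplot2::labs(x = "attrition step", y = "patients retained (log)",
                      title = sprintf("%s cohort attrition", bundle$round))
      ggplot2::ggsave(file.path(directory_path, "fig_attrition.png"), g,
                      width = 10, height = 5, dpi = 96)
    }
    cm <- bundle$tables$fig_code_matrix
    if (nrow(cm) > 0) {
      g <- ggplot2::ggplot(cm, ggplot2::aes(x = .data$stratum, y = .data$site,
                                            fill = .data$value)) +
        ggplot2::geom_tile() +
        ggplot2::labs(x = "procedure code", y = NULL,
                      fill = "patient-year\nproportion",
                      title = "Code utilization by site")
      ggplot2::ggsave(file.path(directory_path, "fig_code_matrix.png"), g,
                      width = 7, height = 5, dpi = 96)
    }
    tc <- bundle$tables$fig_threshold_curves
    if (nrow(tc) > 0) {
      g <- ggplot2::ggplot(tc, ggplot2::aes(x = as.numeric(.data$stratum),
                                            y = .data$value,
                                            colour = .data$site)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "eGFR threshold (mL/min/1.73m2)",
                      y = "proportion with eGFR below threshold",
                      title = "Severity of CKD by site")
      ggplot2::ggsave(file.path(directory_path, "fig_threshold_curves.png"),
                      g, width = 7, height = 5, dpi = 96)
    }
  }
  invisible(directory_path)
}

#' Tailored per-site issue summary
#'
#' Rows ordered by priority (urgent, high, medium, low) then issue id, with
#' the published summary's column set.
#'
#' @param issues Issue tibble.
#' @param site One site id.
#' @return Tibble with columns `unique issue id`, `priority`,
#'   `clinical or data domain`, `data element`, `dq issue`, `info`,
#'   `report reference`.
#' @export
site_summary <- function(issues, site) {
  x <- issues[issues$site_id == site, ]
  if (nrow(x) == 0)
    warning(sprintf("no issues for site: %s", site), call. = FALSE)
  x <- x[order(match(x$priority, PRIORITIES), x$issue_id), ]
  tibble::tibble(`unique issue id` = x$issue_id,
                 priority = x$priority,
                 `clinical or data domain` = x$domain,
                 `data element` = x$element,
                 `dq issue` = x$dq_issue,
                 info = x$info,
                 `report reference` = x$report_ref)
}
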