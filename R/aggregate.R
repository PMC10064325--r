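# Regional benchmarking: median/IQR summaries over facilities,
# per-facility feedback reports, and the end-to-end pipeline driver.

#' Regional summary of facility indicator values
#'
#' Median and quartiles of each indicator over facilities, computed on
#' defined values only (undefined values are excluded and counted
#' separately, never coerced to 0 or infinity). Quartiles use linear
#' interpolation (`stats::quantile` type 7). Indicators with fewer
#' than `min_facilities` defined values are reported with `NA`
#' summaries.
#'
#' @param values A tibble of indicator rows (as produced by
#'   [compute_facility_indicators()] over several facilities) with at
#'   least `indicator_id` and `value` columns.
#' @param min_facilities Minimum number of defined values required to
#'   publish a summary (default 2).
#' @return A tibble with one row per indicator: `indicator_id`,
#'   `n_facilities` (defined values), `n_undefined`, `median`, `q1`,
#'   `q3`.
#' @export
#' @examples
#' x <- tibble::tibble(indicator_id = "QM1", value = c(1, 2, 3, 4, 5))
#' summarize_region(x)  # median 3, IQR (2, 4)
summarize_region <- function(values, min_facilities = 2) {
  qtl <- function(v, p, n) {
    if (n < min_facilities) return(NA_real_)
    unname(quantile(v[!is.na(v)], p, type = 7))
  }
  values |>
    dplyr::group_by(.data$indicator_id) |>
    dplyr::summarise(
      n_facilities = sum(!is.na(.data$value)),
      n_undefined = sum(is.na(.data$value)),
      median = qtl(.data$value, 0.5, .data$n_facilities[1]),
      q1 = qtl(.data$value, 0.25, .data$n_facilities[1]),
      q3 = qtl(.data$value, 0.75, .data$n_facilities[1]),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$indicator_id, c(QM_IDS, PI_IDS)))
}

#' Percentile rank within a regional distribution
#'
#' Midrank convention: a value equal to the regional median of an
#' odd-sized distribution ranks at the 50th percentile; ties share
#' their average rank.
#'
#' @param values Numeric vector of defined regional values.
#' @param x Value(s) to rank.
#' @return Percentile(s) in (0, 100).
#' @export
percentile_rank <- function(values, x) {
  values <- values[!is.na(values)]
  n <- length(values)
  vapply(x, function(xi) {
    if (is.na(xi) || n == 0) return(NA_real_)
    r <- sum(values < xi) + (sum(values == xi) + 1) / 2
    100 * (r - 0.5) / n
  }, numeric(1))
}

#' Per-facility feedback report
#'
#' Joins one facility's 24 indicator values with the regional
#' summaries: facility value, regional median and IQR, percentile
#' rank, compliance class, and an `improvement_target` marker on
#' non-compliant proxy indicators — the table an antimicrobial
#' stewardship network would feed back to the facility to build an
#' action plan.
#'
#' @param facility_values A 24-row tibble for one facility
#'   ([compute_facility_indicators()]).
#' @param all_values Indicator rows for every facility of the region
#'   (used for percentile ranks).
#' @param regional A regional summary from [summarize_region()].
#' @return A tibble with one row per indicator.
#' @export
facility_report <- function(facility_values, all_values, regional) {
  stopifnot(nrow(facility_values) == 24)
  by_ind <- split(all_values$value, all_values$indicator_id)
  facility_values |>
    dplyr::left_join(regional, by = "indicator_id") |>
    dplyr::mutate(
      percentile = mapply(function(id, v) {
        percentile_rank(by_ind[[id]], v)
      }, .data$indicator_id, .data$value),
      status = dplyr::case_when(
        is.na(.data$value) ~ "not_computable",
        .data$compliance_class %in% "non_compliant" ~ "improvement_target",
        TRUE ~ "ok"
      )
    ) |>
    dplyr::select("indicator_id", "facility_id", "numerator", "denominator",
                  "value", "compliance_class", "median", "q1", "q3",
                  "percentile", "status", "flags")
}

#' Run the full claims-to-indicators pipeline
#'
#' Reads the three claims CSVs, validates them, computes the 24
#' indicators for every facility of the analysis year, summarizes the
#' region, and writes `facility_indicators.csv`,
#' `regional_summary.csv`, one feedback report per facility under
#' `reports/`, and `validation_log.csv`. Outputs are deterministic:
#' rerunning on identical inputs reproduces identical files.
#'
#' @param dispensings_path,stays_path,events_path Input CSV paths.
#' @param year Analysis year.
#' @param out_dir Output directory.
#' @param ddd_ref,pack_ref,targets Reference tables (defaults shipped
#'   with the package).
#' @param uc_window,lookback_days,min_denominator,dedupe Engine knobs,
#'   see [compute_facility_indicators()].
#' @param anonymize Replace facility ids by rank-ordered aliases in
#'   the regional outputs (privacy-safe default for sharing).
#' @param strict Stop (after writing the validation log) if validation
#'   fails; if `FALSE`, continue with the clean records.
#' @return Invisibly, a list with `facility_indicators`,
#'   `regional_summary`, `report` (validation).
#' @export
run_pipeline <- function(dispensings_path, stays_path, events_path,
                         year, out_dir,
                         ddd_ref = ddd_reference(),
                         pack_ref = pack_reference(),
                         targets = pi_targets(),
                         uc_window = 7, lookback_days = 180,
                         min_denominator = 0, dedupe = FALSE,
                         anonymize = FALSE, strict = TRUE) {
  loaded <- read_claims_dataset(dispensings_path, stays_path, events_path,
                                analysis_year = year)
  dataset <- loaded$dataset
  report <- loaded$report
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- dplyr::bind_rows(
    dplyr::mutate(report$errors, severity = "error"),
    dplyr::mutate(report$warnings, severity = "warning")
  )
  readr::write_csv(log, file.path(out_dir, "validation_log.csv"))
  if (!report$passed && strict) {
    stop("dataset validation failed: ", nrow(report$errors),
         " error(s); see ", file.path(out_dir, "validation_log.csv"),
         call. = FALSE)
  }
  message(sprintf("loaded %d dispensings, %d stays, %d events (%d errors, %d warnings)",
                  report$n_records["dispensings"], report$n_records["stays"],
                  report$n_records["events"], nrow(report$errors),
                  nrow(report$warnings)))
  if (!any(dataset$dispensings$dispense_date <
             as.Date(sprintf("%d-01-01", year)))) {
    message("no look-back dispensings before ", year,
            ": repeat-quinolone indicator (PI3) may undercount")
  }

  facilities <- sort(unique(dataset$stays$facility_id))
  fi <- dplyr::bind_rows(lapply(facilities, function(f) {
    compute_facility_indicators(dataset, f, ddd_ref, pack_ref, targets,
                                uc_window, lookback_days,
                                min_denominator, dedupe)
  }))
  if (anonymize) {
    alias <- setNames(sprintf("NH%03d", seq_along(facilities)), facilities)
    fi$facility_id <- unname(alias[fi$facility_id])
  }
  readr::write_csv(fi, file.path(out_dir, "facility_indicators.csv"))
  regional <- summarize_region(fi)
  readr::write_csv(regional, file.path(out_dir, "regional_summary.csv"))

  rep_dir <- file.path(out_dir, "reports")
  dir.create(rep_dir, showWarnings = FALSE)
  for (f in unique(fi$facility_id)) {
    fr <- facility_report(fi[fi$facility_id == f, ], fi, regional)
    readr::write_csv(fr, file.path(rep_dir, paste0(f, ".csv")))
  }
  invisible(list(facility_indicators = fi, regional_summary = regional,
                 report = report))
}
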