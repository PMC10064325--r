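# Claims data model: CSV readers with row-level error collection, the
# claims_dataset container, and cross-table validation.

DISPENSING_COLS <- c("record_id", "resident_id", "facility_id",
                     "dispense_date", "atc_code", "route", "n_packages",
                     "units_per_package", "prescriber_id")
STAY_COLS  <- c("resident_id", "facility_id", "entry_date", "exit_date",
                "sex", "birth_year")
EVENT_COLS <- c("resident_id", "facility_id", "event_date", "event_type")

read_raw_csv <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  missing <- setdiff(required_cols, names(raw))
  if (length(missing) > 0) {
    stop("missing mandatory column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw
}

parse_date <- function(x, date_format = "%Y-%m-%d") {
  as.Date(x, format = date_format)
}

row_error <- function(record_id, rule) {
  tibble::tibble(record_id = as.character(record_id), rule = rule)
}

#' Read dispensing records
#'
#' Reads a dispensings CSV (schema:
#' `record_id,resident_id,facility_id,dispense_date,atc_code,route,n_packages,units_per_package,prescriber_id`).
#' Malformed rows (unparseable date, invalid ATC syntax, non-positive
#' package count) are excluded from the data and collected as row
#' errors rather than dropped silently; unrecognized routes map to
#' `"unknown"`, and empty `units_per_package`/`prescriber_id` become
#' `NA` (explicitly unknown, never imputed).
#'
#' @param path Path to the CSV file.
#' @param date_format Date format string (default ISO-8601,
#'   `"%Y-%m-%d"`); claims extracts vary.
#' @return A list with `data` (tibble of clean records) and `errors`
#'   (tibble with columns `record_id`, `rule`).
#' @export
read_dispensings <- function(path, date_format = "%Y-%m-%d") {
  raw <- read_raw_csv(path, DISPENSING_COLS)
  d <- tibble::tibble(
    record_id = raw$record_id,
    resident_id = raw$resident_id,
    facility_id = raw$facility_id,
    dispense_date = parse_date(raw$dispense_date, date_format),
    atc_code = toupper(trimws(raw$atc_code)),
    route = normalize_route(raw$route),
    n_packages = suppressWarnings(as.integer(raw$n_packages)),
    units_per_package = suppressWarnings(as.integer(raw$units_per_package)),
    prescriber_id = dplyr::na_if(raw$prescriber_id, "")
  )
  errors <- dplyr::bind_rows(
    row_error(d$record_id[is.na(d$dispense_date)], "invalid date"),
    row_error(d$record_id[!atc_valid(d$atc_code)], "invalid ATC code"),
    row_error(d$record_id[is.na(d$n_packages) | d$n_packages < 1L],
              "invalid package count")
  )
  keep <- !is.na(d$dispense_date) & atc_valid(d$atc_code) &
    !is.na(d$n_packages) & d$n_packages >= 1L
  list(data = d[keep, ], errors = errors)
}

normalize_route <- function(route) {
  r <- toupper(trimws(route))
  dplyr::case_when(
    r == "ORAL" ~ "oral",
    r %in% c("IV", "IM", "SC") ~ r,
    r == "OTHER" ~ "other",
    TRUE ~ "unknown"
  )
}

normalize_sex <- function(sex) {
  s <- toupper(trimws(sex))
  dplyr::case_when(
    s %in% c("F", "FEMALE") ~ "female",
    s %in% c("M", "MALE") ~ "male",
    TRUE ~ "unknown"
  )
}

#' Read resident stays
#'
#' Reads a stays CSV (schema:
#' `resident_id,facility_id,entry_date,exit_date,sex,birth_year`).
#' An empty `exit_date` is an open-ended stay (the resident is still
#' present; computations truncate it at the end of the analysis
#' period). Sex is normalized to `female`/`male`/`unknown`.
#'
#' @inheritParams read_dispensings
#' @return A list with `data` and `errors` tibbles (errors keyed by
#'   `resident_id`).
#' @export
read_stays <- function(path, date_format = "%Y-%m-%d") {
  raw <- read_raw_csv(path, STAY_COLS)
  s <- tibble::tibble(
    resident_id = raw$resident_id,
    facility_id = raw$facility_id,
    entry_date = parse_date(raw$entry_date, date_format),
    exit_date = parse_date(dplyr::na_if(raw$exit_date, ""), date_format),
    sex = normalize_sex(raw$sex),
    birth_year = suppressWarnings(as.integer(raw$birth_year))
  )
  open <- raw$exit_date == ""
  bad_entry <- is.na(s$entry_date)
  bad_exit <- !open & is.na(s$exit_date)
  inverted <- !is.na(s$entry_date) & !is.na(s$exit_date) &
    s$entry_date > s$exit_date
  errors <- dplyr::bind_rows(
    row_error(s$resident_id[bad_entry | bad_exit], "invalid date"),
    row_error(s$resident_id[inverted], "entry after exit")
  )
  list(data = s[!(bad_entry | bad_exit | inverted), ], errors = errors)
}

#' Read clinical events
#'
#' Reads an events CSV (schema:
#' `resident_id,facility_id,event_date,event_type`) holding non-drug
#' claims: urine cultures and, optionally, flu vaccinations modeled as
#' events. Unknown event types are row errors.
#'
#' @inheritParams read_dispensings
#' @return A list with `data` and `errors` tibbles.
#' @export
read_events <- function(path, date_format = "%Y-%m-%d") {
  raw <- read_raw_csv(path, EVENT_COLS)
  e <- tibble::tibble(
    resident_id = raw$resident_id,
    facility_id = raw$facility_id,
    event_date = parse_date(raw$event_date, date_format),
    event_type = trimws(raw$event_type)
  )
  bad_date <- is.na(e$event_date)
  bad_type <- !e$event_type %in% c("urine_culture", "flu_vaccine")
  errors <- dplyr::bind_rows(
    row_error(e$resident_id[bad_date], "invalid date"),
    row_error(e$resident_id[bad_type], "unknown event type")
  )
  list(data = e[!(bad_date | bad_type), ], errors = errors)
}

#' Assemble a claims dataset
#'
#' Bundles dispensings, stays and events tibbles with the analysis
#' year into a single object consumed by the indicator engines.
#'
#' @param dispensings,stays,events Tibbles as produced by
#'   [read_dispensings()], [read_stays()], [read_events()] (the `data`
#'   element) or by [generate_dataset()].
#' @param analysis_year Integer calendar year the indicators refer to.
#' @return An object of class `claims_dataset`.
#' @export
claims_dataset <- function(dispensings, stays, events = NULL, analysis_year) {
  if (is.null(events)) {
    events <- tibble::tibble(resident_id = character(),
                             facility_id = character(),
                             event_date = as.Date(character()),
                             event_type = character())
  }
  stopifnot(is.data.frame(dispensings), is.data.frame(stays),
            is.data.frame(events), length(analysis_year) == 1L)
  structure(
    list(dispensings = tibble::as_tibble(dispensings),
         stays = tibble::as_tibble(stays),
         events = tibble::as_tibble(events),
         analysis_year = as.integer(analysis_year)),
    class = "claims_dataset"
  )
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset> year", x$analysis_year, "\n")
  cat("  dispensings:", nrow(x$dispensings), "records,",
      dplyr::n_distinct(x$dispensings$facility_id), "facilities\n")
  cat("  stays:      ", nrow(x$stays), "records,",
      dplyr::n_distinct(x$stays$resident_id), "residents\n")
  cat("  events:     ", nrow(x$events), "records\n")
  invisible(x)
}

#' Read a complete claims dataset from CSV files
#'
#' Convenience composition of the three readers plus
#' [validate_dataset()]; reader row errors are carried into the
#' validation report.
#'
#' @param dispensings_path,stays_path,events_path CSV file paths.
#' @param analysis_year Integer calendar year.
#' @inheritParams read_dispensings
#' @return A list with `dataset` (a [claims_dataset()]) and `report`
#'   (a `validation_report`).
#' @export
read_claims_dataset <- function(dispensings_path, stays_path,
                                events_path = NULL, analysis_year,
                                date_format = "%Y-%m-%d") {
  disp <- read_dispensings(dispensings_path, date_format)
  stay <- read_stays(stays_path, date_format)
  ev <- if (is.null(events_path)) {
    list(data = NULL, errors = row_error(character(), character()))
  } else {
    read_events(events_path, date_format)
  }
  dataset <- claims_dataset(disp$data, stay$data, ev$data, analysis_year)
  reader_errors <- dplyr::bind_rows(
    dplyr::mutate(disp$errors, table = "dispensings"),
    dplyr::mutate(stay$errors, table = "stays"),
    dplyr::mutate(ev$errors, table = "events")
  )
  list(dataset = dataset, report = validate_dataset(dataset, reader_errors))
}

#' Write a claims dataset to CSV files
#'
#' Writes `dispensings.csv`, `stays.csv` and `events.csv` in the
#' documented interchange schemas; a read of the written files
#' reproduces the dataset field by field.
#'
#' @param dataset A [claims_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_claims_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset$dispensings[DISPENSING_COLS],
                   file.path(dir, "dispensings.csv"), na = "")
  readr::write_csv(dataset$stays[STAY_COLS],
                   file.path(dir, "stays.csv"), na = "")
  readr::write_csv(dataset$events[EVENT_COLS],
                   file.path(dir, "events.csv"), na = "")
  invisible(dir)
}

#' Validate a claims dataset
#'
#' Cross-table checks: duplicate dispensing `record_id`s and inverted
#' or overlapping stays are errors; dispensings or events for a
#' resident with no recorded stay, or dated outside every stay of that
#' resident, are warnings (they stay in the data but are flagged for
#' audit). The report fails if and only if at least one error exists.
#'
#' @param dataset A [claims_dataset()].
#' @param reader_errors Optional tibble of row errors from the readers
#'   (columns `table`, `record_id`, `rule`) to fold into the report.
#' @return A `validation_report`: list with `n_records`, `errors`,
#'   `warnings` tibbles and a logical `passed`.
#' @export
validate_dataset <- function(dataset, reader_errors = NULL) {
  stopifnot(inherits(dataset, "claims_dataset"))
  d <- dataset$dispensings
  s <- dataset$stays
  e <- dataset$events

  errors <- tibble::tibble(table = character(), record_id = character(),
                           rule = character())
  warnings <- errors
  add <- function(acc, table, ids, rule) {
    if (length(ids) == 0) return(acc)
    dplyr::bind_rows(acc, tibble::tibble(table = table,
                                         record_id = as.character(ids),
                                         rule = rule))
  }

  if (!is.null(reader_errors) && nrow(reader_errors) > 0) {
    errors <- dplyr::bind_rows(errors,
                               reader_errors[, c("table", "record_id", "rule")])
  }

  dup <- d$record_id[duplicated(d$record_id)]
  errors <- add(errors, "dispensings", unique(dup), "duplicate record_id")

  inv <- !is.na(s$exit_date) & s$entry_date > s$exit_date
  errors <- add(errors, "stays", s$resident_id[inv], "entry after exit")

  # overlapping stays of one resident within one facility
  if (nrow(s) > 1) {
    ov <- s |>
      dplyr::mutate(.exit = dplyr::coalesce(.data$exit_date,
                                            as.Date("9999-12-31"))) |>
      dplyr::arrange(.data$resident_id, .data$facility_id, .data$entry_date) |>
      dplyr::group_by(.data$resident_id, .data$facility_id) |>
      dplyr::filter(dplyr::n() > 1,
                    .data$entry_date <= dplyr::lag(.data$.exit,
                                                   default = as.Date("0001-01-01"))) |>
      dplyr::ungroup()
    errors <- add(errors, "stays", unique(ov$resident_id), "overlapping stays")
  }

  ss_entry <- split(s$entry_date, s$resident_id)
  ss_exit <- split(dplyr::coalesce(s$exit_date, as.Date("9999-12-31")),
                   s$resident_id)
  in_any_stay <- function(resident_id, date) {
    mapply(function(rid, dt) {
      en <- ss_entry[[rid]]
      if (is.null(en)) return(FALSE)
      any(dt >= en & dt <= ss_exit[[rid]])
    }, resident_id, date, USE.NAMES = FALSE)
  }

  if (nrow(d) > 0) {
    orphan <- !d$resident_id %in% s$resident_id
    warnings <- add(warnings, "dispensings", d$record_id[orphan],
                    "dispensing for resident with no stay")
    out <- !orphan & !in_any_stay(d$resident_id, d$dispense_date)
    warnings <- add(warnings, "dispensings", d$record_id[out],
                    "dispensing outside recorded stay")
  }
  if (nrow(e) > 0) {
    orphan_e <- !e$resident_id %in% s$resident_id
    warnings <- add(warnings, "events", e$resident_id[orphan_e],
                    "event for resident with no stay")
    out_e <- !orphan_e & !in_any_stay(e$resident_id, e$event_date)
    warnings <- add(warnings, "events", e$resident_id[out_e],
                    "event outside recorded stay")
  }

  structure(
    list(
      n_records = c(dispensings = nrow(d), stays = nrow(s), events = nrow(e)),
      errors = errors,
      warnings = warnings,
      passed = nrow(errors) == 0
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>",
      if (x$passed) "PASS" else "FAIL", "\n")
  cat("  records:", paste(names(x$n_records), x$n_records,
                          sep = "=", collapse = ", "), "\n")
  cat("  errors:", nrow(x$errors), " warnings:", nrow(x$warnings), "\n")
  if (nrow(x$errors) > 0) print(head(x$errors, 10))
  invisible(x)
}
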