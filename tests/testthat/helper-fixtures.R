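# Small programmatic builders for hand-assembled datasets.

mk_stay <- function(resident_id, entry, exit = NA, sex = "female",
                    facility_id = "f1", birth_year = 1930L) {
  tibble::tibble(resident_id = resident_id, facility_id = facility_id,
                 entry_date = as.Date(entry),
                 exit_date = as.Date(exit), sex = sex,
                 birth_year = birth_year)
}

mk_disp <- function(resident_id, date, atc, route = "oral",
                    n_packages = 1L, units = 14L, facility_id = "f1",
                    record_id = NULL) {
  n <- max(length(resident_id), length(date), length(atc))
  tibble::tibble(
    record_id = record_id %||% sprintf("r%03d", seq_len(n)),
    resident_id = resident_id, facility_id = facility_id,
    dispense_date = as.Date(date), atc_code = atc, route = route,
    n_packages = as.integer(n_packages),
    units_per_package = as.integer(units), prescriber_id = "g1")
}

mk_event <- function(resident_id, date, type = "urine_culture",
                     facility_id = "f1") {
  tibble::tibble(resident_id = resident_id, facility_id = facility_id,
                 event_date = as.Date(date), event_type = type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

demo_dataset <- function() {
  demo <- system.file("extdata", "demo", package = "nhabx")
  read_claims_dataset(file.path(demo, "dispensings.csv"),
                      file.path(demo, "stays.csv"),
                      file.path(demo, "events.csv"),
                      analysis_year = 2019)
}
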