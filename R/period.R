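# Analysis periods and exposure denominators. A period is a tibble of
# closed date intervals (the cold-weather season has two blocks), with
# a label attribute.

make_period <- function(start, end, label) {
  p <- tibble::tibble(start = as.Date(start), end = as.Date(end))
  stopifnot(all(p$start <= p$end))
  attr(p, "label") <- label
  p
}

#' Analysis periods
#'
#' `analysis_period()` is the calendar year; `cold_season()` is
#' January-March plus October-December; `hot_season()` is
#' April-September. All intervals are closed (both endpoints count).
#'
#' @param year Integer calendar year.
#' @return A tibble of `start`/`end` date intervals with a `label`
#'   attribute.
#' @export
analysis_period <- function(year) {
  make_period(sprintf("%d-01-01", year), sprintf("%d-12-31", year),
              as.character(year))
}

#' @rdname analysis_period
#' @export
cold_season <- function(year) {
  make_period(c(sprintf("%d-01-01", year), sprintf("%d-10-01", year)),
              c(sprintf("%d-03-31", year), sprintf("%d-12-31", year)),
              "cold")
}

#' @rdname analysis_period
#' @export
hot_season <- function(year) {
  make_period(sprintf("%d-04-01", year), sprintf("%d-09-30", year), "hot")
}

date_in_period <- function(date, period) {
  out <- rep(FALSE, length(date))
  for (k in seq_len(nrow(period))) {
    out <- out | (date >= period$start[k] & date <= period$end[k])
  }
  out
}

stay_overlap_days <- function(entry, exit, period) {
  # inclusive day count of (stay intersect period); open exits (NA)
  # truncated at the period end
  total <- numeric(length(entry))
  for (k in seq_len(nrow(period))) {
    lo <- pmax(entry, period$start[k])
    hi <- pmin(dplyr::coalesce(exit, period$end[k]), period$end[k])
    total <- total + pmax(0, as.numeric(hi - lo) + 1)
  }
  total
}

#' Resident-days of exposure
#'
#' Sum over stays of the number of calendar days each stay shares with
#' the period, counting both endpoints (a same-day entry and exit is
#' one resident-day). Open-ended stays are truncated at the period
#' end. This is the denominator of all per-100-resident-days rates.
#'
#' @param stays A stays tibble.
#' @param facility_id Facility to restrict to.
#' @param period A period from [analysis_period()] and friends.
#' @return A non-negative number of resident-days.
#' @export
resident_days <- function(stays, facility_id, period) {
  s <- stays[stays$facility_id == facility_id, ]
  if (nrow(s) == 0) return(0)
  sum(stay_overlap_days(s$entry_date, s$exit_date, period))
}

#' Residents present during a period
#'
#' Number of distinct residents with at least one stay-day overlapping
#' the period, regardless of length of stay.
#'
#' @inheritParams resident_days
#' @return A non-negative integer count.
#' @export
residents_present <- function(stays, facility_id, period) {
  s <- stays[stays$facility_id == facility_id, ]
  if (nrow(s) == 0) return(0L)
  ok <- stay_overlap_days(s$entry_date, s$exit_date, period) > 0
  dplyr::n_distinct(s$resident_id[ok])
}
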