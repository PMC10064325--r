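# The 14 quantity metrics (QM1-QM14) for one facility and one
# analysis year. Rate metrics are expressed per 100 resident-days;
# share metrics (QM3, QM12, QM14) on a 0-100 scale. The counting unit
# is the reimbursed dispensing: one row = one drug dispensed on one
# date ("prescription" in the indicator wording).

QM_IDS <- paste0("QM", 1:14)
PI_IDS <- paste0("PI", 1:10)

indicator_value <- function(indicator_id, facility_id, numerator,
                            denominator, scale = 100, flags = character()) {
  defined <- denominator > 0
  tibble::tibble(
    indicator_id = indicator_id,
    facility_id = facility_id,
    numerator = numerator,
    denominator = denominator,
    value = if (defined) scale * numerator / denominator else NA_real_,
    flags = paste(
      c(flags, if (!defined) "zero_denominator"), collapse = ";")
  )
}

facility_year_dispensings <- function(dataset, facility_id) {
  period <- analysis_period(dataset$analysis_year)
  d <- dataset$dispensings
  d[d$facility_id == facility_id &
      date_in_period(d$dispense_date, period), ]
}

facility_year_events <- function(dataset, facility_id, type,
                                 period = NULL) {
  period <- period %||% analysis_period(dataset$analysis_year)
  e <- dataset$events
  e[e$facility_id == facility_id & e$event_type == type &
      date_in_period(e$event_date, period), ]
}

# class behind each count/DDD rate metric
QM_CLASS <- c(QM1 = "ALL_ABX", QM2 = "ALL_ABX",
              QM4 = "AMC", QM5 = "AMC", QM6 = "CEPH", QM7 = "CEPH",
              QM8 = "FQ", QM9 = "FQ", QM10 = "MLSK", QM11 = "MLSK")
QM_DDD <- c("QM2", "QM5", "QM7", "QM9", "QM11")

#' Compute one quantity metric
#'
#' The fourteen metrics cover global antibiotic consumption (QM1-QM3),
#' broad-spectrum and second-line classes by prescription count and
#' DDD (QM4-QM11), the parenteral route share (QM12), and urine
#' cultures (QM13-QM14):
#'
#' * QM1/QM2 - J01 prescriptions / DDDs per 100 resident-days
#' * QM3 - residents with at least one J01 prescription per 100
#'   residents of the year
#' * QM4/QM5 - amoxicillin/clavulanate, QM6/QM7 - cephalosporins,
#'   QM8/QM9 - quinolones, QM10/QM11 - MLSK (count / DDD per 100
#'   resident-days)
#' * QM12 - parenteral (IV, IM, SC) J01 prescriptions per 100 oral +
#'   parenteral J01 prescriptions (unknown routes excluded from both
#'   terms, flagged)
#' * QM13 - urine cultures per 100 resident-days
#' * QM14 - residents with at least one urine culture per 100
#'   residents of the year, regardless of length of stay
#'
#' Zero (or suppressed) denominators yield an undefined value with a
#' flag. Dispensings whose ATC code is missing from the DDD reference
#' are excluded from DDD metrics and flagged (coverage warning).
#'
#' @param dataset A validated [claims_dataset()].
#' @param facility_id Facility to compute for.
#' @param qm_id One of `"QM1"` ... `"QM14"`.
#' @param ddd_ref DDD reference table ([ddd_reference()]).
#' @param min_denominator Denominators strictly below this are
#'   suppressed (value undefined); default 0, i.e. only true zero.
#' @param dedupe If `TRUE`, collapse duplicate same-day, same-drug,
#'   same-resident rows to one before counting.
#' @return A one-row tibble: `indicator_id`, `facility_id`,
#'   `numerator`, `denominator`, `value`, `flags`.
#' @export
compute_qm <- function(dataset, facility_id, qm_id,
                       ddd_ref = ddd_reference(),
                       min_denominator = 0, dedupe = FALSE) {
  stopifnot(inherits(dataset, "claims_dataset"))
  if (!qm_id %in% QM_IDS) stop("unknown quantity metric id: ", qm_id,
                               call. = FALSE)
  year <- dataset$analysis_year
  period <- analysis_period(year)
  d <- facility_year_dispensings(dataset, facility_id)
  if (dedupe) {
    d <- dplyr::distinct(d, .data$resident_id, .data$dispense_date,
                         .data$atc_code, .keep_all = TRUE)
  }
  rd <- resident_days(dataset$stays, facility_id, period)
  flags <- character()

  val <- function(num, den, scale = 100) {
    suppressed <- den > 0 && den < min_denominator
    if (suppressed) {
      flags <- c(flags, "suppressed_denominator")
      den <- 0
    }
    indicator_value(qm_id, facility_id, num, den, scale, flags)
  }

  if (qm_id %in% names(QM_CLASS)) {
    sel <- d[in_class(d$atc_code, QM_CLASS[[qm_id]]), ]
    if (qm_id %in% QM_DDD) {
      ddd <- ddd_per_record(sel$atc_code, sel$n_packages,
                            sel$units_per_package, ddd_ref)
      miss <- is.na(ddd) | is.na(sel$units_per_package)
      if (any(miss)) {
        flags <- c(flags, sprintf("ddd_reference_missing:%d", sum(miss)))
      }
      return(val(sum(ddd[!miss]), rd))
    }
    return(val(nrow(sel), rd))
  }

  switch(qm_id,
    QM3 = {
      abx <- d[in_class(d$atc_code, "ALL_ABX"), ]
      val(dplyr::n_distinct(abx$resident_id),
          residents_present(dataset$stays, facility_id, period))
    },
    QM12 = {
      abx <- d[in_class(d$atc_code, "ALL_ABX"), ]
      cat_ <- route_category(abx$route)
      if (any(cat_ == "other")) {
        flags <- c(flags, sprintf("route_unknown_excluded:%d",
                                  sum(cat_ == "other")))
      }
      val(sum(cat_ == "parenteral"), sum(cat_ != "other"))
    },
    QM13 = {
      uc <- facility_year_events(dataset, facility_id, "urine_culture")
      val(nrow(uc), rd)
    },
    QM14 = {
      uc <- facility_year_events(dataset, facility_id, "urine_culture")
      val(dplyr::n_distinct(uc$resident_id),
          residents_present(dataset$stays, facility_id, period))
    }
  )
}

#' Compute all 14 quantity metrics
#'
#' @inheritParams compute_qm
#' @return A 14-row tibble, ids `QM1` ... `QM14`, each row carrying
#'   its numerator and denominator.
#' @export
compute_all_qms <- function(dataset, facility_id,
                            ddd_ref = ddd_reference(),
                            min_denominator = 0, dedupe = FALSE) {
  dplyr::bind_rows(lapply(QM_IDS, function(id) {
    compute_qm(dataset, facility_id, id, ddd_ref,
               min_denominator = min_denominator, dedupe = dedupe)
  }))
}
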