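# The 10 proxy indicators (PI1-PI10) and compliance classification
# against their consensus target bands. Ratio indicators (PI1, PI2,
# PI6) are plain ratios; the rest are on a 0-100 scale.

uti_first_line <- list(
  male = list(num = c("NITROFURANTOIN", "FOSFOMYCIN_TROM", "PIVMECILLINAM",
                      "AMOX", "AMC"),
              den = c("FQ", "CEPH", "SXT")),
  female = list(num = c("NITROFURANTOIN", "FOSFOMYCIN_TROM", "PIVMECILLINAM"),
                den = "FQ")
)

in_any_class <- function(atc_code, class_ids) {
  out <- rep(FALSE, length(atc_code))
  for (cl in class_ids) out <- out | in_class(atc_code, cl)
  out
}

resident_sex <- function(stays) {
  stays |>
    dplyr::filter(.data$sex != "unknown") |>
    dplyr::distinct(.data$resident_id, .data$sex)
}

# TRUE where the resident has a urine culture dated 0..window days
# before the dispensing
uc_linked <- function(dispensings, events, window = 7) {
  uc <- events[events$event_type == "urine_culture", ]
  uc_by_res <- split(uc$event_date, uc$resident_id)
  mapply(function(rid, dt) {
    ucd <- uc_by_res[[rid]]
    if (is.null(ucd)) return(FALSE)
    any(dt - ucd >= 0 & dt - ucd <= window)
  }, dispensings$resident_id, dispensings$dispense_date,
  USE.NAMES = FALSE)
}

#' Urinary-tract-infection drug-choice ratio (PI1, PI2)
#'
#' Among antibiotic dispensings in the week following a urine culture
#' (dispensing dated 0-7 days after a culture of the same resident,
#' both terms windowed), the ratio of first-choice urinary drugs to
#' the drugs to avoid, pooled over the facility-year and restricted by
#' sex. For male residents (PI1) the numerator is nitrofurantoin +
#' fosfomycin/trometamol + pivmecillinam + amoxicillin +
#' amoxicillin/clavulanate and the denominator quinolones +
#' cephalosporins + co-trimoxazole; for female residents (PI2) the
#' numerator is nitrofurantoin + fosfomycin/trometamol + pivmecillinam
#' and the denominator quinolones. Plain ratio (no scaling); a zero
#' denominator makes the value undefined with a flag.
#'
#' @param dataset A validated [claims_dataset()].
#' @param facility_id Facility to compute for.
#' @param sex `"male"` (PI1) or `"female"` (PI2).
#' @param uc_window Linkage window in days after the culture
#'   (default 7, inclusive of day 0).
#' @return A one-row indicator tibble.
#' @export
pi_uti_choice_ratio <- function(dataset, facility_id, sex, uc_window = 7) {
  if (!sex %in% c("male", "female")) {
    stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  }
  id <- if (sex == "male") "PI1" else "PI2"
  classes <- uti_first_line[[sex]]
  d <- facility_year_dispensings(dataset, facility_id)
  d <- dplyr::inner_join(d, resident_sex(dataset$stays), by = "resident_id")
  d <- d[d$sex == sex, ]
  linked <- if (nrow(d) > 0) uc_linked(d, dataset$events, uc_window) else logical()
  num <- sum(linked & in_any_class(d$atc_code, classes$num))
  den <- sum(linked & in_any_class(d$atc_code, classes$den))
  indicator_value(id, facility_id, num, den, scale = 1)
}

#' Repeat quinolone prescriptions (PI3)
#'
#' Share (0-100) of the year's quinolone (J01M) dispensings for which
#' the same resident had another quinolone dispensing 1-180 days
#' earlier ("prescribed quinolones in the preceding 6 months"). The
#' look-back crosses into the prior calendar year, so the dataset may
#' include a look-back extract; if no dispensing predates the analysis
#' year the value carries a completeness flag.
#'
#' @inheritParams pi_uti_choice_ratio
#' @param lookback_days Look-back horizon in days (default 180).
#' @return A one-row indicator tibble.
#' @export
pi_repeat_quinolone <- function(dataset, facility_id, lookback_days = 180) {
  year_start <- as.Date(sprintf("%d-01-01", dataset$analysis_year))
  d <- facility_year_dispensings(dataset, facility_id)
  fq_year <- d[in_class(d$atc_code, "FQ"), ]
  all_d <- dataset$dispensings
  fq_all <- all_d[all_d$facility_id == facility_id &
                    in_class(all_d$atc_code, "FQ"), ]
  fq_by_res <- split(fq_all$dispense_date, fq_all$resident_id)
  has_prior <- if (nrow(fq_year) == 0) logical() else {
    mapply(function(rid, dt) {
      gaps <- as.numeric(dt - fq_by_res[[rid]])
      any(gaps >= 1 & gaps <= lookback_days)
    }, fq_year$resident_id, fq_year$dispense_date, USE.NAMES = FALSE)
  }
  flags <- if (!any(all_d$dispense_date < year_start)) "no_lookback_data"
  indicator_value("PI3", facility_id, sum(has_prior), nrow(fq_year),
                  flags = flags %||% character())
}

#' Seasonal variation of prescriptions (PI4, PI5)
#'
#' `(cold-season count / hot-season count - 1) * 100` for all
#' antibiotics (PI4, `class_id = "ALL_ABX"`) or
#' amoxicillin/clavulanate (PI5, `class_id = "AMC"`). Cold season is
#' January-March plus October-December of the analysis year; hot
#' season April-September. A zero hot-season count makes the value
#' undefined with a flag.
#'
#' @inheritParams pi_uti_choice_ratio
#' @param class_id `"ALL_ABX"` or `"AMC"`.
#' @return A one-row indicator tibble.
#' @export
pi_seasonal_variation <- function(dataset, facility_id, class_id = "ALL_ABX") {
  if (!class_id %in% c("ALL_ABX", "AMC")) {
    stop("`class_id` must be \"ALL_ABX\" (PI4) or \"AMC\" (PI5)",
         call. = FALSE)
  }
  id <- if (class_id == "ALL_ABX") "PI4" else "PI5"
  year <- dataset$analysis_year
  d <- facility_year_dispensings(dataset, facility_id)
  d <- d[in_class(d$atc_code, class_id), ]
  cold <- sum(date_in_period(d$dispense_date, cold_season(year)))
  hot <- sum(date_in_period(d$dispense_date, hot_season(year)))
  out <- indicator_value(id, facility_id, cold, hot, scale = 100)
  out$value <- if (hot > 0) (cold / hot - 1) * 100 else NA_real_
  out
}

#' First-line versus second-line antibiotics (PI6)
#'
#' Ratio of amoxicillin + amoxicillin/clavulanate dispensings to
#' quinolone + cephalosporin + MLSK dispensings over the facility-year
#' (plain ratio).
#'
#' @inheritParams pi_uti_choice_ratio
#' @return A one-row indicator tibble.
#' @export
pi_first_vs_second_line <- function(dataset, facility_id) {
  d <- facility_year_dispensings(dataset, facility_id)
  num <- sum(in_any_class(d$atc_code, c("AMOX", "AMC")))
  den <- sum(in_any_class(d$atc_code, c("FQ", "CEPH", "MLSK")))
  indicator_value("PI6", facility_id, num, den, scale = 1)
}

#' Prolonged antibiotic courses (PI7)
#'
#' Among dispensings of the eight monitored drugs (amoxicillin,
#' amoxicillin/clavulanate, cefuroxime, cefpodoxime, roxithromycin,
#' clarithromycin, pristinamycin, nitrofurantoin), the share (0-100)
#' with an estimated treatment duration strictly greater than 7 days.
#' Duration is estimated from the quantity of packages dispensed
#' ([estimate_duration_days()]); a course of exactly 7.0 days is not
#' prolonged. Monitored-drug dispensings missing from the pack
#' reference are excluded with a warning flag.
#'
#' @inheritParams pi_uti_choice_ratio
#' @param pack_ref Pack reference table ([pack_reference()]).
#' @return A one-row indicator tibble.
#' @export
pi_prolonged_courses <- function(dataset, facility_id,
                                 pack_ref = pack_reference()) {
  d <- facility_year_dispensings(dataset, facility_id)
  d <- d[in_class(d$atc_code, "PI7_LIST"), ]
  dur <- duration_per_record(d$atc_code, d$n_packages,
                             d$units_per_package, pack_ref)
  flags <- character()
  if (anyNA(dur)) {
    flags <- sprintf("pack_reference_missing:%d", sum(is.na(dur)))
    d <- d[!is.na(dur), ]
    dur <- dur[!is.na(dur)]
  }
  indicator_value("PI7", facility_id, sum(dur > 7.0), nrow(d),
                  flags = flags)
}

#' Same-day NSAID co-prescription (PI8)
#'
#' Share (0-100) of antibiotic (J01) dispensings for which the same
#' resident has a systemic NSAID (M01A) dispensing on the identical
#' calendar date.
#'
#' @inheritParams pi_uti_choice_ratio
#' @return A one-row indicator tibble.
#' @export
pi_nsaid_coprescription <- function(dataset, facility_id) {
  d <- facility_year_dispensings(dataset, facility_id)
  abx <- d[in_class(d$atc_code, "ALL_ABX"), ]
  nsaid <- d[in_class(d$atc_code, "NSAID"), ]
  key <- paste(nsaid$resident_id, nsaid$dispense_date)
  hit <- paste(abx$resident_id, abx$dispense_date) %in% key
  indicator_value("PI8", facility_id, sum(hit), nrow(abx))
}

#' Flu-vaccine coverage (PI9)
#'
#' Flu vaccines dispensed during the cold-weather season per 100
#' residents staying in the facility during the cold season (at least
#' one stay-day). Vaccines are counted as `flu_vaccine` events or as
#' dispensings with an influenza-vaccine ATC code (J07BB prefix); the
#' numerator counts dispensings, not distinct residents, so values
#' above 100 are possible and flagged (`over_coverage`). Set
#' `distinct_residents = TRUE` for a per-resident variant; it deviates
#' from the dispensing-count definition and is flagged as such.
#'
#' @inheritParams pi_uti_choice_ratio
#' @param distinct_residents Count vaccinated residents rather than
#'   vaccine dispensings (non-standard variant).
#' @return A one-row indicator tibble.
#' @export
pi_flu_coverage <- function(dataset, facility_id,
                            distinct_residents = FALSE) {
  year <- dataset$analysis_year
  cold <- cold_season(year)
  ev <- facility_year_events(dataset, facility_id, "flu_vaccine", cold)
  d <- dataset$dispensings
  dv <- d[d$facility_id == facility_id &
            in_class(d$atc_code, "FLU_VACCINE") &
            date_in_period(d$dispense_date, cold), ]
  flags <- character()
  if (distinct_residents) {
    num <- dplyr::n_distinct(c(ev$resident_id, dv$resident_id))
    flags <- "distinct_resident_variant"
  } else {
    num <- nrow(ev) + nrow(dv)
  }
  den <- residents_present(dataset$stays, facility_id, cold)
  out <- indicator_value("PI9", facility_id, num, den, flags = flags)
  if (!is.na(out$value) && out$value > 100) {
    out$flags <- paste(c(out$flags[out$flags != ""], "over_coverage"),
                       collapse = ";")
  }
  out
}

#' Oral cephalosporin share (PI10)
#'
#' Share (0-100) of oral cephalosporin (J01D) dispensings among oral +
#' parenteral (IV, IM, SC) cephalosporin dispensings. Records with an
#' unknown or other route are excluded from both terms and flagged.
#'
#' @inheritParams pi_uti_choice_ratio
#' @return A one-row indicator tibble.
#' @export
pi_oral_cephalosporins <- function(dataset, facility_id) {
  d <- facility_year_dispensings(dataset, facility_id)
  ceph <- d[in_class(d$atc_code, "CEPH"), ]
  cat_ <- route_category(ceph$route)
  flags <- character()
  if (any(cat_ == "other")) {
    flags <- sprintf("route_unknown_excluded:%d", sum(cat_ == "other"))
  }
  indicator_value("PI10", facility_id, sum(cat_ == "oral"),
                  sum(cat_ != "other"), flags = flags)
}

#' Consensus target bands for the proxy indicators
#'
#' Machine-readable encoding of each indicator's target: direction,
#' an optimal bound and (where stated) an acceptable bound, with the
#' comparison operator of each bound (`eq` = exactly equal, `lt`/`gt`
#' strict, `ge` inclusive), following the printed symbols exactly
#' (e.g. prolonged courses: optimal <5, acceptable <20; flu coverage:
#' optimal >=90).
#'
#' @param path Optional replacement CSV (columns
#'   `indicator_id,direction,optimal_op,optimal_bound,acceptable_op,acceptable_bound`).
#' @return A 10-row tibble.
#' @export
pi_targets <- function(path = NULL) {
  path <- path %||% ref_path("pi_targets.csv")
  readr::read_csv(path, col_types = readr::cols(
    indicator_id = readr::col_character(),
    direction = readr::col_character(),
    optimal_op = readr::col_character(),
    optimal_bound = readr::col_double(),
    acceptable_op = readr::col_character(),
    acceptable_bound = readr::col_double()
  ))
}

meets_bound <- function(value, op, bound) {
  switch(op,
         eq = value == bound,
         lt = value < bound,
         le = value <= bound,
         gt = value > bound,
         ge = value >= bound,
         stop("unknown comparison operator: ", op, call. = FALSE))
}

#' Classify an indicator value against its target
#'
#' Three-band classification (`optimal`, `acceptable`,
#' `non_compliant`) where both bounds exist, two-band (`optimal` /
#' `non_compliant`) otherwise; an undefined (NA) value is classed
#' `undefined`. "Optimal 0" means a value of exactly zero.
#'
#' @param indicator_id Character vector of PI ids (`"PI1"` ...
#'   `"PI10"`).
#' @param value Numeric vector of indicator values (NA = undefined).
#' @param targets Target table from [pi_targets()].
#' @return Character vector of compliance classes.
#' @export
#' @examples
#' classify_compliance("PI7", c(4, 5, 20, NA))
classify_compliance <- function(indicator_id, value, targets = pi_targets()) {
  stopifnot(length(indicator_id) == length(value) ||
              length(indicator_id) == 1L)
  if (length(indicator_id) == 1L) {
    indicator_id <- rep(indicator_id, length(value))
  }
  i <- match(indicator_id, targets$indicator_id)
  if (anyNA(i)) {
    stop("no target defined for: ",
         paste(unique(indicator_id[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  vapply(seq_along(value), function(k) {
    t <- targets[i[k], ]
    if (is.na(value[k])) return("undefined")
    if (meets_bound(value[k], t$optimal_op, t$optimal_bound)) return("optimal")
    if (!is.na(t$acceptable_bound) &&
        meets_bound(value[k], t$acceptable_op, t$acceptable_bound)) {
      return("acceptable")
    }
    "non_compliant"
  }, character(1))
}

#' Compute all 10 proxy indicators with compliance classes
#'
#' @inheritParams pi_uti_choice_ratio
#' @inheritParams pi_prolonged_courses
#' @inheritParams pi_repeat_quinolone
#' @param targets Target table from [pi_targets()].
#' @return A 10-row tibble (ids `PI1` ... `PI10`) with a
#'   `compliance_class` column.
#' @export
compute_all_pis <- function(dataset, facility_id,
                            pack_ref = pack_reference(),
                            targets = pi_targets(),
                            uc_window = 7, lookback_days = 180) {
  out <- dplyr::bind_rows(
    pi_uti_choice_ratio(dataset, facility_id, "male", uc_window),
    pi_uti_choice_ratio(dataset, facility_id, "female", uc_window),
    pi_repeat_quinolone(dataset, facility_id, lookback_days),
    pi_seasonal_variation(dataset, facility_id, "ALL_ABX"),
    pi_seasonal_variation(dataset, facility_id, "AMC"),
    pi_first_vs_second_line(dataset, facility_id),
    pi_prolonged_courses(dataset, facility_id, pack_ref),
    pi_nsaid_coprescription(dataset, facility_id),
    pi_flu_coverage(dataset, facility_id),
    pi_oral_cephalosporins(dataset, facility_id)
  )
  out$compliance_class <- classify_compliance(out$indicator_id, out$value,
                                              targets)
  out
}

#' Compute the full 24-indicator set for one facility-year
#'
#' Binds the 14 quantity metrics and the 10 classified proxy
#' indicators into one facility indicator set (quantity metrics have
#' no target, so their `compliance_class` is `NA`).
#'
#' @inheritParams compute_all_pis
#' @inheritParams compute_qm
#' @return A 24-row tibble.
#' @export
compute_facility_indicators <- function(dataset, facility_id,
                                        ddd_ref = ddd_reference(),
                                        pack_ref = pack_reference(),
                                        targets = pi_targets(),
                                        uc_window = 7, lookback_days = 180,
                                        min_denominator = 0,
                                        dedupe = FALSE) {
  qm <- compute_all_qms(dataset, facility_id, ddd_ref,
                        min_denominator = min_denominator, dedupe = dedupe)
  qm$compliance_class <- NA_character_
  pi <- compute_all_pis(dataset, facility_id, pack_ref, targets,
                        uc_window, lookback_days)
  dplyr::bind_rows(qm, pi)
}
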