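# ATC hierarchy matching, indicator drug classes, DDD arithmetic and
# package-based duration estimation.

#' Validate ATC code syntax
#'
#' An ATC code is hierarchical: anatomical group (letter + 2 digits),
#' then optionally a therapeutic subgroup letter, a pharmacological
#' subgroup letter, and a 2-digit chemical-substance suffix
#' (e.g. `"J01"`, `"J01C"`, `"J01CR"`, `"J01CR02"`).
#'
#' @param code Character vector of candidate ATC codes.
#' @return Logical vector, `TRUE` where the syntax is valid.
#' @export
#' @examples
#' atc_valid(c("J01", "J01CR02", "j01", "J1X"))
atc_valid <- function(code) {
  grepl("^[A-Z][0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?$", code)
}

#' Test whether an ATC code falls under a prefix
#'
#' @param code Character vector of full ATC codes.
#' @param prefix A single ATC prefix (any hierarchy level).
#' @return Logical vector: `TRUE` where `code` starts with `prefix`.
#' @export
#' @examples
#' atc_matches("J01CR02", "J01")
atc_matches <- function(code, prefix) {
  if (length(prefix) != 1L || !atc_valid(prefix)) {
    stop("`prefix` must be a single syntactically valid ATC prefix, got: ",
         paste(prefix, collapse = ", "), call. = FALSE)
  }
  bad <- !atc_valid(code)
  if (any(bad)) {
    stop("malformed ATC code(s): ", paste(unique(code[bad]), collapse = ", "),
         call. = FALSE)
  }
  startsWith(code, prefix)
}

#' Drug-class prefix sets used by the indicators
#'
#' Returns the ATC prefix sets behind every class filter: all systemic
#' antibacterials (J01), amoxicillin/clavulanate, cephalosporins,
#' quinolones, MLSK (macrolides, lincosamides, streptogramins,
#' ketolides), the first-line urinary-tract drugs, co-trimoxazole,
#' systemic NSAIDs, influenza vaccines, and the eight named drugs whose
#' course duration is monitored (amoxicillin, amoxicillin/clavulanate,
#' cefuroxime, cefpodoxime, roxithromycin, clarithromycin,
#' pristinamycin, nitrofurantoin).
#'
#' @return Named list of character vectors of ATC prefixes.
#' @export
drug_class_prefixes <- function() {
  list(
    ALL_ABX         = "J01",
    AMC             = "J01CR02",
    CEPH            = "J01D",
    FQ              = "J01M",
    MLSK            = "J01F",
    AMOX            = "J01CA04",
    NITROFURANTOIN  = "J01XE01",
    FOSFOMYCIN_TROM = "J01XX01",
    PIVMECILLINAM   = "J01CA08",
    SXT             = "J01EE01",
    NSAID           = "M01A",
    FLU_VACCINE     = "J07BB",
    PI7_LIST        = c("J01CA04", "J01CR02", "J01DC02", "J01DD13",
                        "J01FA06", "J01FA09", "J01FG01", "J01XE01")
  )
}

#' Class membership of ATC codes
#'
#' @param atc_code Character vector of full ATC codes.
#' @param class_id One of the class ids returned by
#'   [drug_class_prefixes()], e.g. `"ALL_ABX"`, `"AMC"`, `"PI7_LIST"`.
#' @return Logical vector: `TRUE` where the code starts with any prefix
#'   of the class.
#' @export
#' @examples
#' in_class(c("J01CR02", "J05AB01"), "ALL_ABX")
in_class <- function(atc_code, class_id) {
  classes <- drug_class_prefixes()
  if (length(class_id) != 1L || !class_id %in% names(classes)) {
    stop("unknown drug class id: ", paste(class_id, collapse = ", "),
         call. = FALSE)
  }
  prefixes <- classes[[class_id]]
  out <- rep(FALSE, length(atc_code))
  for (p in prefixes) out <- out | atc_matches(atc_code, p)
  out
}

ref_path <- function(file) {
  system.file("extdata", file, package = "nhabx", mustWork = TRUE)
}

#' Defined-daily-dose reference table
#'
#' Maps full ATC codes to the mass per dispensed unit and the WHO-style
#' defined daily dose (DDD), both in grams. The shipped default covers
#' the drugs the indicators name; it is editable reference data, keyed
#' by 7-character ATC code.
#'
#' @param path Optional path to a replacement CSV with columns
#'   `atc_code,unit_strength_g,ddd_g`.
#' @return A tibble with columns `atc_code`, `unit_strength_g`, `ddd_g`.
#' @export
ddd_reference <- function(path = NULL) {
  path <- path %||% ref_path("ddd_reference.csv")
  ref <- readr::read_csv(path, col_types = readr::cols(
    atc_code = readr::col_character(),
    unit_strength_g = readr::col_double(),
    ddd_g = readr::col_double()
  ))
  if (any(!atc_valid(ref$atc_code)) || anyDuplicated(ref$atc_code)) {
    stop("DDD reference: ATC codes must be valid and unique", call. = FALSE)
  }
  if (any(ref$unit_strength_g <= 0) || any(ref$ddd_g <= 0)) {
    stop("DDD reference: strengths and DDD values must be > 0", call. = FALSE)
  }
  ref
}

#' Package-content reference table
#'
#' Maps full ATC codes to the number of units per package and the
#' assumed units taken per day, the basis of package-based
#' treatment-duration estimation (prescription durations are absent
#' from reimbursement data; only the number of packages dispensed is
#' recorded).
#'
#' @param path Optional path to a replacement CSV with columns
#'   `atc_code,units_per_package,units_per_day`.
#' @return A tibble with columns `atc_code`, `units_per_package`,
#'   `units_per_day`.
#' @export
pack_reference <- function(path = NULL) {
  path <- path %||% ref_path("pack_reference.csv")
  ref <- readr::read_csv(path, col_types = readr::cols(
    atc_code = readr::col_character(),
    units_per_package = readr::col_double(),
    units_per_day = readr::col_double()
  ))
  if (any(!atc_valid(ref$atc_code)) || anyDuplicated(ref$atc_code)) {
    stop("pack reference: ATC codes must be valid and unique", call. = FALSE)
  }
  if (any(ref$units_per_package <= 0) || any(ref$units_per_day <= 0)) {
    stop("pack reference: units per package and per day must be > 0",
         call. = FALSE)
  }
  ref
}

#' Total DDD of a dispensing
#'
#' `n_packages * units_per_package * unit_strength / DDD` for each
#' record. Errors if any ATC code is absent from the reference; the
#' indicator engine uses [ddd_per_record()] instead, which returns `NA`
#' for uncovered codes so they can be excluded with a coverage warning.
#'
#' @param atc_code,n_packages,units_per_package Parallel vectors
#'   describing the dispensings.
#' @param ref A DDD reference table from [ddd_reference()].
#' @return Numeric vector of DDDs.
#' @export
#' @examples
#' ref <- tibble::tibble(atc_code = "J01CA04",
#'                       unit_strength_g = 0.5, ddd_g = 1)
#' total_ddd("J01CA04", 2, 14, ref)  # 2 x 14 x 0.5 / 1 = 14
total_ddd <- function(atc_code, n_packages, units_per_package, ref) {
  out <- ddd_per_record(atc_code, n_packages, units_per_package, ref)
  if (anyNA(out)) {
    missing <- unique(atc_code[is.na(out)])
    stop("ATC code(s) absent from DDD reference: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname total_ddd
#' @export
ddd_per_record <- function(atc_code, n_packages, units_per_package, ref) {
  i <- match(atc_code, ref$atc_code)
  n_packages * units_per_package * ref$unit_strength_g[i] / ref$ddd_g[i]
}

#' Estimate treatment duration from packages dispensed
#'
#' `n_packages * units_per_package / units_per_day`, with
#' `units_per_package` taken from the record when known and from the
#' pack reference otherwise. Errors if any ATC code is absent from the
#' reference; [duration_per_record()] is the `NA`-returning variant
#' used by the engine.
#'
#' @param atc_code,n_packages,units_per_package Parallel vectors;
#'   `units_per_package` may be `NA` (unknown in the claim).
#' @param ref A pack reference table from [pack_reference()].
#' @return Numeric vector of estimated days of treatment.
#' @export
#' @examples
#' ref <- tibble::tibble(atc_code = "J01CA04",
#'                       units_per_package = 14, units_per_day = 2)
#' estimate_duration_days("J01CA04", 1, NA, ref)  # 14 / 2 = 7
estimate_duration_days <- function(atc_code, n_packages,
                                   units_per_package = NA, ref) {
  out <- duration_per_record(atc_code, n_packages, units_per_package, ref)
  bad <- is.na(out) & !is.na(atc_code)
  if (any(bad)) {
    stop("ATC code(s) absent from pack reference: ",
         paste(unique(atc_code[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname estimate_duration_days
#' @export
duration_per_record <- function(atc_code, n_packages,
                                units_per_package = NA, ref) {
  i <- match(atc_code, ref$atc_code)
  upp <- ifelse(is.na(units_per_package),
                ref$units_per_package[i], units_per_package)
  n_packages * upp / ref$units_per_day[i]
}

#' Route category of a dispensing
#'
#' IV, IM and SC routes form the parenteral family; `other` and
#' `unknown` map to `other` and are excluded from both terms of
#' route-share indicators.
#'
#' @param route Character vector with values among
#'   `oral, IV, IM, SC, other, unknown`.
#' @return Character vector with values among `oral`, `parenteral`,
#'   `other`.
#' @export
route_category <- function(route) {
  ok <- c("oral", "IV", "IM", "SC", "other", "unknown")
  bad <- !route %in% ok
  if (any(bad)) {
    stop("invalid route value(s): ", paste(unique(route[bad]), collapse = ", "),
         call. = FALSE)
  }
  dplyr::case_when(
    route %in% c("IV", "IM", "SC") ~ "parenteral",
    route == "oral" ~ "oral",
    TRUE ~ "other"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
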