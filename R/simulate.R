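# Synthetic nursing-home claims generator with analytically known
# ground truth. It emulates the structure of national reimbursement
# data: per-resident dispensing streams with ATC codes, dates, routes
# and package counts, linked to stays, urine cultures and flu
# vaccinations.
#
# The central design choice: all antibiotic dispensings of a resident
# come from one Poisson budget at `abx_rate` per 100 resident-days;
# urinary-tract-infection episodes (urine-culture-linked), drug class,
# route and package count are marks on that budget, never extra
# insertions. Expected QM1 therefore equals abx_rate exactly, and the
# seasonal day-weighting (cold days weighted m * H/C, with H and C the
# hot/cold-season day totals) makes the expected cold/hot count ratio
# exactly the seasonal multiplier m, so expected PI4 is (m - 1) * 100
# for full-year stays.

# code pools per generator class; OTHER covers J01 drugs outside the
# four monitored classes
GEN_POOLS <- list(
  AMOX = "J01CA04",
  AMC = "J01CR02",
  CEPH = c("J01DC02", "J01DD13"),
  FQ = c("J01MA01", "J01MA02"),
  MLSK = c("J01FA06", "J01FA09", "J01FG01"),
  OTHER = c("J01AA02", "J01EE01")
)

#' Simulation parameters
#'
#' Validated parameter set for [generate_dataset()]. The default
#' preset ("france-2019-like") places rates near plausible regional
#' magnitudes for community nursing homes — facility size around 90
#' residents, three-quarters women, mean age 87, 0.52 antibiotic
#' dispensings and 0.15 urine cultures per 100 resident-days, ~30%
#' winter excess, ~9% parenteral share, 81% flu coverage — and is
#' illustrative, not a reproduction claim.
#'
#' @param n_facilities Number of facilities.
#' @param mean_residents,sd_residents Facility size distribution
#'   (normal, rounded, floored at 5).
#' @param sex_ratio_female Probability a resident is female.
#' @param mean_age,sd_age Resident age distribution (years).
#' @param turnover Fraction of residents with a partial-year stay
#'   (half admissions, half departures).
#' @param abx_rate Expected antibiotic (J01) dispensings per 100
#'   resident-days.
#' @param class_mixture Probabilities over generator classes
#'   `AMOX, AMC, CEPH, FQ, MLSK, OTHER` for non-UTI dispensings
#'   (must sum to 1).
#' @param route_parenteral Probability of an IV/IM/SC route.
#' @param seasonal_multiplier Target ratio of expected cold-season to
#'   hot-season dispensing counts (m >= 0).
#' @param p_two_packages Probability a dispensing has 2 packages
#'   (otherwise 1).
#' @param p_uti Probability a dispensing is a urinary-tract-infection
#'   episode (drug drawn from the sex-specific UTI mixture).
#' @param p_uc_before_abx Probability a UTI episode has a urine
#'   culture 0-7 days before the dispensing.
#' @param uti_mixture_male,uti_mixture_female Probabilities over ATC
#'   codes for UTI episodes, by sex (each sums to 1).
#' @param uc_rate_standalone Urine cultures per 100 resident-days not
#'   followed by treatment.
#' @param repeat_fq_prob Probability a quinolone dispensing after the
#'   resident's first is re-dated to within 180 days of the previous
#'   one (a repeat course).
#' @param nsaid_coprescription_prob Probability an antibiotic
#'   dispensing has a same-day systemic NSAID dispensing.
#' @param flu_coverage_prob Probability a resident present in the cold
#'   season receives one flu vaccine during it.
#' @param lookback_days Length of the pre-year dispensing extract
#'   emitted for long-stay residents (repeat-quinolone look-back).
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_facilities = 20,
                              mean_residents = 90,
                              sd_residents = 35,
                              sex_ratio_female = 0.75,
                              mean_age = 87,
                              sd_age = 7,
                              turnover = 0.25,
                              abx_rate = 0.52,
                              class_mixture = c(AMOX = 0.28, AMC = 0.17,
                                                CEPH = 0.14, FQ = 0.07,
                                                MLSK = 0.10, OTHER = 0.24),
                              route_parenteral = 0.09,
                              seasonal_multiplier = 1.3,
                              p_two_packages = 0.5,
                              p_uti = 0.15,
                              p_uc_before_abx = 0.8,
                              uti_mixture_male = c(
                                J01XE01 = 0.02, J01XX01 = 0.01,
                                J01CA08 = 0.01, J01CA04 = 0.08,
                                J01CR02 = 0.08, J01MA01 = 0.25,
                                J01MA02 = 0.20, J01DC02 = 0.10,
                                J01DD13 = 0.10, J01DD04 = 0.05,
                                J01EE01 = 0.10),
                              uti_mixture_female = c(
                                J01XE01 = 0.12, J01XX01 = 0.08,
                                J01CA08 = 0.02, J01CA04 = 0.13,
                                J01CR02 = 0.15, J01MA01 = 0.15,
                                J01MA02 = 0.15, J01DC02 = 0.08,
                                J01DD13 = 0.07, J01EE01 = 0.05),
                              uc_rate_standalone = 0.09,
                              repeat_fq_prob = 0.2,
                              nsaid_coprescription_prob = 0.02,
                              flu_coverage_prob = 0.81,
                              lookback_days = 180) {
  p <- as.list(environment())
  probs <- c(p$sex_ratio_female, p$turnover, p$route_parenteral,
             p$p_two_packages, p$p_uti, p$p_uc_before_abx,
             p$repeat_fq_prob, p$nsaid_coprescription_prob,
             p$flu_coverage_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p$abx_rate < 0 || p$uc_rate_standalone < 0 ||
      p$seasonal_multiplier < 0) {
    stop("rates and the seasonal multiplier must be >= 0", call. = FALSE)
  }
  if (abs(sum(p$class_mixture) - 1) > 1e-8 ||
      !setequal(names(p$class_mixture), names(GEN_POOLS))) {
    stop("class_mixture must sum to 1 over classes ",
         paste(names(GEN_POOLS), collapse = ", "), call. = FALSE)
  }
  for (mx in list(p$uti_mixture_male, p$uti_mixture_female)) {
    if (abs(sum(mx) - 1) > 1e-8 || any(mx < 0) || any(!atc_valid(names(mx)))) {
      stop("UTI mixtures must be named by valid ATC codes and sum to 1",
           call. = FALSE)
    }
  }
  if (p$n_facilities < 1 || p$mean_residents < 5) {
    stop("need at least 1 facility and mean_residents >= 5", call. = FALSE)
  }
  structure(p, class = "simulation_params")
}

# seasonal day weights making E[cold count] / E[hot count] = m for a
# full-year stay
season_weights <- function(days, year, m) {
  all_days <- seq(as.Date(sprintf("%d-01-01", year)),
                  as.Date(sprintf("%d-12-31", year)), by = "day")
  hot <- date_in_period(all_days, hot_season(year))
  H <- sum(hot)
  C <- sum(!hot)
  ifelse(date_in_period(days, cold_season(year)), m * H / C, 1)
}

#' Generate a synthetic claims dataset
#'
#' Draws facilities, resident stays, antibiotic dispensings, urine
#' cultures, NSAID co-dispensings, flu vaccinations and a pre-year
#' look-back extract according to `params` (see
#' [simulation_params()] for the generative model). Fully reproducible
#' from `seed`.
#'
#' @param params A [simulation_params()] object.
#' @param seed Integer random seed.
#' @param year Analysis year (default 2019).
#' @return A list with `dataset` (a [claims_dataset()]), `truth` (the
#'   [expected_indicators()] table), and `tags` (tibble mapping
#'   dispensing `record_id` to its generative origin: `base`, `uti`,
#'   `fq_repeat`, `nsaid`, `lookback`).
#' @export
generate_dataset <- function(params, seed, year = 2019) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(seed)
  p <- params
  year_start <- as.Date(sprintf("%d-01-01", year))
  year_end <- as.Date(sprintf("%d-12-31", year))
  cold <- cold_season(year)
  pack_ref <- pack_reference()
  upp <- setNames(pack_ref$units_per_package, pack_ref$atc_code)

  stays_l <- list(); disp_l <- list(); events_l <- list()
  for (i in seq_len(p$n_facilities)) {
    fid <- sprintf("F%03d", i)
    n_res <- max(5L, as.integer(round(rnorm(1, p$mean_residents,
                                            p$sd_residents))))
    rid <- sprintf("%s-R%04d", fid, seq_len(n_res))
    sex <- ifelse(runif(n_res) < p$sex_ratio_female, "female", "male")
    birth_year <- as.integer(year - pmax(65, round(rnorm(n_res, p$mean_age,
                                                         p$sd_age))))
    entry <- rep(year_start - p$lookback_days, n_res)
    exit <- rep(year_end, n_res)
    partial <- runif(n_res) < p$turnover
    admission <- partial & runif(n_res) < 0.5
    departure <- partial & !admission
    entry[admission] <- year_start + sample.int(364, sum(admission),
                                                replace = TRUE)
    exit[departure] <- year_start + sample.int(364, sum(departure),
                                               replace = TRUE) - 1
    stays_l[[fid]] <- tibble::tibble(
      resident_id = rid, facility_id = fid, entry_date = entry,
      exit_date = exit, sex = sex, birth_year = birth_year)

    for (j in seq_len(n_res)) {
      res <- simulate_resident(rid[j], fid, sex[j], entry[j], exit[j],
                               year, p, upp, cold)
      disp_l[[rid[j]]] <- res$dispensings
      events_l[[rid[j]]] <- res$events
    }
  }

  disp <- dplyr::bind_rows(disp_l)
  if (nrow(disp) > 0) {
    disp$record_id <- sprintf("D%06d", seq_len(nrow(disp)))
  }
  tags <- tibble::tibble(record_id = disp$record_id,
                         origin = disp$origin %||% character())
  disp$origin <- NULL
  dataset <- claims_dataset(disp, dplyr::bind_rows(stays_l),
                            dplyr::bind_rows(events_l), year)
  list(dataset = dataset, truth = expected_indicators(params), tags = tags)
}

# ATC-code probabilities of the non-UTI dispensing stream: class
# mixture spread uniformly over each class's code pool
base_code_probs <- function(class_mixture) {
  unlist(lapply(names(GEN_POOLS), function(cl) {
    pool <- GEN_POOLS[[cl]]
    setNames(rep(class_mixture[[cl]] / length(pool), length(pool)), pool)
  }))
}

# one resident's dispensing and event streams
simulate_resident <- function(rid, fid, sex, entry, exit, year, p, upp,
                              cold) {
  year_start <- as.Date(sprintf("%d-01-01", year))
  year_end <- as.Date(sprintf("%d-12-31", year))
  days <- seq(max(entry, year_start), min(exit, year_end), by = "day")
  w <- season_weights(days, year, p$seasonal_multiplier)
  prescriber <- sprintf("%s-G%02d", fid, sample.int(8, 1))

  base_probs <- base_code_probs(p$class_mixture)
  n <- rpois(1, p$abx_rate / 100 * length(days))
  dates <- sort(sample(days, n, replace = TRUE, prob = w))
  is_uti <- runif(n) < p$p_uti
  uti_mix <- if (sex == "female") p$uti_mixture_female else p$uti_mixture_male
  code <- character(n)
  code[!is_uti] <- sample(names(base_probs), sum(!is_uti), replace = TRUE,
                          prob = base_probs)
  code[is_uti] <- sample(names(uti_mix), sum(is_uti), replace = TRUE,
                         prob = uti_mix)
  origin <- ifelse(is_uti, "uti", "base")

  # repeat quinolone courses: re-date later base quinolones to within
  # the look-back window of the previous one
  fq <- which(in_class(code, "FQ") & !is_uti)
  if (length(fq) >= 2) {
    for (k in fq[-1]) {
      prev <- max(fq[fq < k])
      if (runif(1) < p$repeat_fq_prob) {
        cand <- dates[prev] + sample.int(p$lookback_days, 1)
        if (cand <= min(exit, year_end)) {
          dates[k] <- cand
          origin[k] <- "fq_repeat"
        }
      }
    }
  }

  parenteral <- runif(n) < p$route_parenteral
  route <- ifelse(parenteral,
                  c("IV", "IM", "SC")[sample.int(3, n, replace = TRUE)],
                  "oral")
  n_packages <- 1L + rbinom(n, 1, p$p_two_packages)

  # urine cultures preceding UTI episodes (clamped into the stay-year)
  uc_idx <- which(is_uti & runif(n) < p$p_uc_before_abx)
  uc_offsets <- sample(0:7, length(uc_idx), replace = TRUE)
  uc_dates <- pmax(dates[uc_idx] - uc_offsets, days[1])

  # standalone urine cultures (not followed by treatment)
  n_uc0 <- rpois(1, p$uc_rate_standalone / 100 * length(days))
  uc0_dates <- sample(days, n_uc0, replace = TRUE)

  # same-day NSAID co-dispensings
  nsaid_idx <- which(runif(n) < p$nsaid_coprescription_prob)
  nsaid_code <- c("M01AE01", "M01AB05")[sample.int(2, length(nsaid_idx),
                                                   replace = TRUE)]

  # look-back extract before the analysis year
  lb_dates <- as.Date(character()); lb_code <- character()
  if (entry < year_start) {
    lb_days <- seq(entry, year_start - 1, by = "day")
    n_lb <- rpois(1, p$abx_rate / 100 * length(lb_days))
    lb_dates <- sample(lb_days, n_lb, replace = TRUE)
    lb_code <- sample(names(base_probs), n_lb, replace = TRUE,
                      prob = base_probs)
  }

  all_code <- c(code, nsaid_code, lb_code)
  all_dates <- c(dates, dates[nsaid_idx], lb_dates)
  all_route <- c(route, rep("oral", length(nsaid_idx) + length(lb_code)))
  all_np <- c(n_packages,
              rep(1L, length(nsaid_idx)),
              1L + rbinom(length(lb_code), 1, p$p_two_packages))
  all_origin <- c(origin, rep("nsaid", length(nsaid_idx)),
                  rep("lookback", length(lb_code)))

  dispensings <- tibble::tibble(
    record_id = NA_character_,
    resident_id = rid,
    facility_id = fid,
    dispense_date = all_dates,
    atc_code = all_code,
    route = all_route,
    n_packages = all_np,
    units_per_package = as.integer(unname(upp[all_code])),
    prescriber_id = prescriber,
    origin = all_origin
  )

  # flu vaccination during the cold season
  flu_dates <- as.Date(character())
  cold_days <- days[date_in_period(days, cold)]
  if (length(cold_days) > 0 && runif(1) < p$flu_coverage_prob) {
    flu_dates <- cold_days[sample.int(length(cold_days), 1)]
  }
  events <- tibble::tibble(
    resident_id = rid, facility_id = fid,
    event_date = c(uc_dates, uc0_dates, flu_dates),
    event_type = c(rep("urine_culture", length(uc_dates) + length(uc0_dates)),
                   rep("flu_vaccine", length(flu_dates)))
  )
  list(dispensings = dispensings, events = events)
}

#' Analytic expected indicator values implied by the parameters
#'
#' Closed-form expectations for the indicators the generative model
#' pins down directly; the `basis` column records how each value is
#' derived:
#'
#' * `analytic` — exact expectation of the ratio's terms under the
#'   model (for long stays): QM1 = `abx_rate`; QM4/6/8/10 =
#'   `abx_rate` times the effective class probability; QM2/5/7/9/11
#'   from the DDD content of the effective code mixture; QM12 =
#'   100 x parenteral route probability; QM13 = standalone culture
#'   rate + `abx_rate * p_uti * p_uc_before_abx`; PI4/PI5 =
#'   `(m - 1) * 100`; PI6 from the effective class mixture; PI7 from
#'   the package-count distribution and the pack reference; PI8 =
#'   100 x co-prescription probability; PI9 = 100 x coverage
#'   probability.
#' * `approximate` — ratio of expectations or a thinning
#'   approximation: PI1/PI2 from the sex-specific UTI mixtures
#'   (ignores accidental urine-culture links of non-UTI dispensings);
#'   PI3 from the repeat probability times the expected share of
#'   non-first quinolone dispensings.
#' * `none` — no closed form (QM3 and QM14 depend on the per-resident
#'   distribution of stay lengths).
#'
#' @param params A [simulation_params()] object.
#' @param pack_ref Pack reference used for the duration expectation.
#' @param ddd_ref DDD reference used for the DDD expectations.
#' @return A 24-row tibble: `indicator_id`, `expected`, `basis`.
#' @export
expected_indicators <- function(params, pack_ref = pack_reference(),
                                ddd_ref = ddd_reference()) {
  p <- params
  # effective probability of each ATC code for an in-year dispensing
  base_codes <- base_code_probs(p$class_mixture)
  uti_names <- union(names(p$uti_mixture_female), names(p$uti_mixture_male))
  uti_codes <- p$sex_ratio_female * pad_mix(p$uti_mixture_female, uti_names) +
    (1 - p$sex_ratio_female) * pad_mix(p$uti_mixture_male, uti_names)
  all_names <- union(names(base_codes), names(uti_codes))
  eff <- (1 - p$p_uti) * pad_mix(base_codes, all_names) +
    p$p_uti * pad_mix(uti_codes, all_names)

  class_p <- function(class_id) sum(eff[in_class(all_names, class_id)])
  mean_packages <- 1 + p$p_two_packages
  ddd_of <- function(codes) {
    i <- match(codes, ddd_ref$atc_code)
    j <- match(codes, pack_ref$atc_code)
    mean_packages * pack_ref$units_per_package[j] *
      ddd_ref$unit_strength_g[i] / ddd_ref$ddd_g[i]
  }
  ddd_rate <- function(class_id) {
    sel <- in_class(all_names, class_id)
    p$abx_rate * sum(eff[sel] * ddd_of(all_names[sel]))
  }

  # PI7: probability a monitored-drug dispensing exceeds 7 estimated days
  pi7_sel <- in_class(all_names, "PI7_LIST")
  dur1 <- duration_per_record(all_names[pi7_sel], 1, NA, pack_ref)
  dur2 <- duration_per_record(all_names[pi7_sel], 2, NA, pack_ref)
  pi7 <- 100 * sum(eff[pi7_sel] * (p$p_two_packages * (dur2 > 7) +
                                     (1 - p$p_two_packages) * (dur1 > 7))) /
    sum(eff[pi7_sel])

  uti_ratio <- function(mix, num_classes, den_classes) {
    codes <- names(mix)
    sum(mix[in_any_class(codes, num_classes)]) /
      sum(mix[in_any_class(codes, den_classes)])
  }
  # PI3 approximation, full-year stay: a year quinolone has a prior
  # quinolone within 180 days either naturally (Poisson stream of all
  # quinolone dispensings, look-back included) or because it was
  # re-dated as a deliberate repeat course
  fq_day_all <- p$abx_rate / 100 * class_p("FQ")
  fq_year_base <- p$abx_rate / 100 * 365 * (1 - p$p_uti) *
    sum(pad_mix(base_codes, all_names)[in_class(all_names, "FQ")])
  fq_year_all <- 365 * fq_day_all
  q_natural <- 1 - exp(-p$lookback_days * fq_day_all)
  f_repeat <- if (fq_year_all > 0) {
    p$repeat_fq_prob * (fq_year_base - 1 + exp(-fq_year_base)) / fq_year_all
  } else 0
  pi3 <- if (fq_year_all > 0) {
    100 * (1 - (1 - f_repeat) * (1 - q_natural))
  } else NA_real_

  tibble::tibble(
    indicator_id = c(QM_IDS, PI_IDS),
    expected = c(
      p$abx_rate,                               # QM1
      ddd_rate("ALL_ABX"),                      # QM2
      NA_real_,                                 # QM3
      p$abx_rate * class_p("AMC"),              # QM4
      ddd_rate("AMC"),                          # QM5
      p$abx_rate * class_p("CEPH"),             # QM6
      ddd_rate("CEPH"),                         # QM7
      p$abx_rate * class_p("FQ"),               # QM8
      ddd_rate("FQ"),                           # QM9
      p$abx_rate * class_p("MLSK"),             # QM10
      ddd_rate("MLSK"),                         # QM11
      100 * p$route_parenteral,                 # QM12
      p$uc_rate_standalone +
        p$abx_rate * p$p_uti * p$p_uc_before_abx, # QM13
      NA_real_,                                 # QM14
      uti_ratio(p$uti_mixture_male,
                c("NITROFURANTOIN", "FOSFOMYCIN_TROM", "PIVMECILLINAM",
                  "AMOX", "AMC"),
                c("FQ", "CEPH", "SXT")),        # PI1
      uti_ratio(p$uti_mixture_female,
                c("NITROFURANTOIN", "FOSFOMYCIN_TROM", "PIVMECILLINAM"),
                "FQ"),                          # PI2
      pi3,                                      # PI3
      (p$seasonal_multiplier - 1) * 100,        # PI4
      (p$seasonal_multiplier - 1) * 100,        # PI5
      (class_p("AMOX") + class_p("AMC")) /
        (class_p("FQ") + class_p("CEPH") + class_p("MLSK")), # PI6
      pi7,                                      # PI7
      100 * p$nsaid_coprescription_prob,        # PI8
      100 * p$flu_coverage_prob,                # PI9
      100 * (1 - p$route_parenteral)            # PI10 = 100 * P(oral route)
    ),
    basis = c("analytic", "analytic", "none", rep("analytic", 10), "none",
              "approximate", "approximate", "approximate",
              "analytic", "analytic", "analytic", "analytic", "analytic",
              "analytic", "analytic")
  )
}

pad_mix <- function(mix, all_names) {
  out <- setNames(rep(0, length(all_names)), all_names)
  out[names(mix)] <- mix
  out
}
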