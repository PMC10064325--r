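# Naive reference implementation of all 24 indicators: explicit
# per-record loops and day-by-day counting, independent of the engine
# code paths. Used to cross-check the vectorized engines exactly on
# random micro-datasets.

oracle_cold <- function(d) {
  m <- as.integer(format(d, "%m"))
  m <= 3 | m >= 10
}

oracle_indicators <- function(ds, fid, ddd_ref = ddd_reference(),
                              pack_ref = pack_reference()) {
  year <- ds$analysis_year
  ys <- as.Date(sprintf("%d-01-01", year))
  ye <- as.Date(sprintf("%d-12-31", year))

  # --- exposure denominators, day-by-day ---
  rd <- 0
  res_present <- character()
  cold_res <- character()
  for (i in seq_len(nrow(ds$stays))) {
    s <- ds$stays[i, ]
    if (s$facility_id != fid) next
    lo <- max(s$entry_date, ys)
    hi <- min(if (is.na(s$exit_date)) ye else s$exit_date, ye)
    if (hi < lo) next
    days <- seq(lo, hi, by = "day")
    rd <- rd + length(days)
    res_present <- union(res_present, s$resident_id)
    if (any(oracle_cold(days))) cold_res <- union(cold_res, s$resident_id)
  }
  n_res <- length(res_present)

  sex_of <- list()
  for (i in seq_len(nrow(ds$stays))) {
    s <- ds$stays[i, ]
    if (s$sex != "unknown") sex_of[[s$resident_id]] <- s$sex
  }

  # --- per-dispensing bookkeeping ---
  d <- ds$dispensings
  in_fac_year <- rep(FALSE, nrow(d))
  for (i in seq_len(nrow(d))) {
    in_fac_year[i] <- d$facility_id[i] == fid &&
      d$dispense_date[i] >= ys && d$dispense_date[i] <= ye
  }
  is_j01 <- startsWith(d$atc_code, "J01")
  ddd_i <- match(d$atc_code, ddd_ref$atc_code)
  pack_i <- match(d$atc_code, pack_ref$atc_code)

  count_class <- function(prefixes) {
    n <- 0
    for (i in seq_len(nrow(d))) {
      if (in_fac_year[i] && any(startsWith(d$atc_code[i], prefixes))) {
        n <- n + 1
      }
    }
    n
  }
  ddd_class <- function(prefixes) {
    tot <- 0
    for (i in seq_len(nrow(d))) {
      if (in_fac_year[i] && any(startsWith(d$atc_code[i], prefixes)) &&
          !is.na(ddd_i[i]) && !is.na(d$units_per_package[i])) {
        tot <- tot + d$n_packages[i] * d$units_per_package[i] *
          ddd_ref$unit_strength_g[ddd_i[i]] / ddd_ref$ddd_g[ddd_i[i]]
      }
    }
    tot
  }
  rate <- function(num, den, scale = 100) {
    if (den > 0) scale * num / den else NA_real_
  }

  # residents with >=1 J01 / urine culture
  abx_res <- character(); uc_res <- character(); n_uc <- 0
  for (i in seq_len(nrow(d))) {
    if (in_fac_year[i] && is_j01[i]) abx_res <- union(abx_res, d$resident_id[i])
  }
  e <- ds$events
  for (i in seq_len(nrow(e))) {
    if (e$facility_id[i] == fid && e$event_type[i] == "urine_culture" &&
        e$event_date[i] >= ys && e$event_date[i] <= ye) {
      n_uc <- n_uc + 1
      uc_res <- union(uc_res, e$resident_id[i])
    }
  }

  # QM12: route share among oral+parenteral J01
  n_par <- 0; n_oralpar <- 0
  for (i in seq_len(nrow(d))) {
    if (!in_fac_year[i] || !is_j01[i]) next
    if (d$route[i] %in% c("IV", "IM", "SC")) {
      n_par <- n_par + 1; n_oralpar <- n_oralpar + 1
    } else if (d$route[i] == "oral") {
      n_oralpar <- n_oralpar + 1
    }
  }

  # PI1/PI2: urine-culture-linked drug choice by sex
  linked <- rep(FALSE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!in_fac_year[i]) next
    for (j in seq_len(nrow(e))) {
      if (e$event_type[j] == "urine_culture" &&
          e$resident_id[j] == d$resident_id[i]) {
        gap <- as.numeric(d$dispense_date[i] - e$event_date[j])
        if (gap >= 0 && gap <= 7) linked[i] <- TRUE
      }
    }
  }
  uti_ratio <- function(sex, num_pref, den_pref) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(d))) {
      if (!in_fac_year[i] || !linked[i]) next
      s <- sex_of[[d$resident_id[i]]]
      if (is.null(s) || s != sex) next
      if (any(startsWith(d$atc_code[i], num_pref))) num <- num + 1
      if (any(startsWith(d$atc_code[i], den_pref))) den <- den + 1
    }
    rate(num, den, scale = 1)
  }
  pi1 <- uti_ratio("male",
                   c("J01XE01", "J01XX01", "J01CA08", "J01CA04", "J01CR02"),
                   c("J01M", "J01D", "J01EE01"))
  pi2 <- uti_ratio("female", c("J01XE01", "J01XX01", "J01CA08"), "J01M")

  # PI3: repeat quinolones within 180 days
  n_fq <- 0; n_rep <- 0
  for (i in seq_len(nrow(d))) {
    if (!in_fac_year[i] || !startsWith(d$atc_code[i], "J01M")) next
    n_fq <- n_fq + 1
    prior <- FALSE
    for (j in seq_len(nrow(d))) {
      if (j != i && d$facility_id[j] == fid &&
          d$resident_id[j] == d$resident_id[i] &&
          startsWith(d$atc_code[j], "J01M")) {
        gap <- as.numeric(d$dispense_date[i] - d$dispense_date[j])
        if (gap >= 1 && gap <= 180) prior <- TRUE
      }
    }
    if (prior) n_rep <- n_rep + 1
  }
  pi3 <- rate(n_rep, n_fq)

  # PI4/PI5: seasonal variation
  seasonal <- function(prefixes) {
    ncold <- 0; nhot <- 0
    for (i in seq_len(nrow(d))) {
      if (!in_fac_year[i] || !any(startsWith(d$atc_code[i], prefixes))) next
      if (oracle_cold(d$dispense_date[i])) ncold <- ncold + 1 else nhot <- nhot + 1
    }
    if (nhot > 0) (ncold / nhot - 1) * 100 else NA_real_
  }

  # PI6
  pi6 <- rate(count_class(c("J01CA04", "J01CR02")),
              count_class(c("J01M", "J01D", "J01F")), scale = 1)

  # PI7: prolonged courses of the eight monitored drugs
  pi7_pref <- c("J01CA04", "J01CR02", "J01DC02", "J01DD13",
                "J01FA06", "J01FA09", "J01FG01", "J01XE01")
  n7 <- 0; n7_long <- 0
  for (i in seq_len(nrow(d))) {
    if (!in_fac_year[i] || !any(startsWith(d$atc_code[i], pi7_pref))) next
    if (is.na(pack_i[i])) next  # excluded, no reference entry
    upp <- d$units_per_package[i]
    if (is.na(upp)) upp <- pack_ref$units_per_package[pack_i[i]]
    dur <- d$n_packages[i] * upp / pack_ref$units_per_day[pack_i[i]]
    n7 <- n7 + 1
    if (dur > 7) n7_long <- n7_long + 1
  }
  pi7 <- rate(n7_long, n7)

  # PI8: same-day NSAID co-prescription
  n_abx <- 0; n_co <- 0
  for (i in seq_len(nrow(d))) {
    if (!in_fac_year[i] || !is_j01[i]) next
    n_abx <- n_abx + 1
    co <- FALSE
    for (j in seq_len(nrow(d))) {
      if (in_fac_year[j] && startsWith(d$atc_code[j], "M01A") &&
          d$resident_id[j] == d$resident_id[i] &&
          d$dispense_date[j] == d$dispense_date[i]) co <- TRUE
    }
    if (co) n_co <- n_co + 1
  }
  pi8 <- rate(n_co, n_abx)

  # PI9: flu coverage in cold season
  n_flu <- 0
  for (i in seq_len(nrow(e))) {
    if (e$facility_id[i] == fid && e$event_type[i] == "flu_vaccine" &&
        e$event_date[i] >= ys && e$event_date[i] <= ye &&
        oracle_cold(e$event_date[i])) n_flu <- n_flu + 1
  }
  for (i in seq_len(nrow(d))) {
    if (d$facility_id[i] == fid && startsWith(d$atc_code[i], "J07BB") &&
        d$dispense_date[i] >= ys && d$dispense_date[i] <= ye &&
        oracle_cold(d$dispense_date[i])) n_flu <- n_flu + 1
  }
  pi9 <- rate(n_flu, length(cold_res))

  # PI10: oral cephalosporin share
  n_ceph_oral <- 0; n_ceph <- 0
  for (i in seq_len(nrow(d))) {
    if (!in_fac_year[i] || !startsWith(d$atc_code[i], "J01D")) next
    if (d$route[i] == "oral") { n_ceph_oral <- n_ceph_oral + 1; n_ceph <- n_ceph + 1 }
    else if (d$route[i] %in% c("IV", "IM", "SC")) n_ceph <- n_ceph + 1
  }
  pi10 <- rate(n_ceph_oral, n_ceph)

  c(QM1 = rate(count_class("J01"), rd),
    QM2 = rate(ddd_class("J01"), rd),
    QM3 = rate(length(abx_res), n_res),
    QM4 = rate(count_class("J01CR02"), rd),
    QM5 = rate(ddd_class("J01CR02"), rd),
    QM6 = rate(count_class("J01D"), rd),
    QM7 = rate(ddd_class("J01D"), rd),
    QM8 = rate(count_class("J01M"), rd),
    QM9 = rate(ddd_class("J01M"), rd),
    QM10 = rate(count_class("J01F"), rd),
    QM11 = rate(ddd_class("J01F"), rd),
    QM12 = rate(n_par, n_oralpar),
    QM13 = rate(n_uc, rd),
    QM14 = rate(length(uc_res), n_res),
    PI1 = pi1, PI2 = pi2, PI3 = pi3,
    PI4 = seasonal("J01"), PI5 = seasonal("J01CR02"),
    PI6 = pi6, PI7 = pi7, PI8 = pi8, PI9 = pi9, PI10 = pi10)
}

# random micro-dataset spanning every indicator's code paths
random_micro_dataset <- function(seed) {
  set.seed(seed)
  year <- 2019
  ys <- as.Date("2019-01-01")
  n_res <- sample(3:8, 1)
  fid <- "f1"
  rid <- sprintf("p%02d", seq_len(n_res))
  sex <- sample(c("female", "male"), n_res, replace = TRUE)
  entry <- ys + sample(c(0, 0, 0, sample(0:300, 1)), n_res, replace = TRUE)
  len <- sample(30:365, n_res, replace = TRUE)
  exit <- pmin(entry + len, as.Date("2019-12-31"))
  exit[sample(n_res, 1)] <- NA  # one open-ended stay
  stays <- tibble::tibble(resident_id = rid, facility_id = fid,
                          entry_date = entry, exit_date = exit,
                          sex = sex, birth_year = 1930L)

  codes <- c("J01CA04", "J01CR02", "J01DC02", "J01DD04", "J01MA01",
             "J01MA02", "J01FA09", "J01FG01", "J01XE01", "J01XX01",
             "J01CA08", "J01EE01", "J01AA02", "M01AE01", "J05AB01",
             "J07BB02")
  n_disp <- sample(10:60, 1)
  disp <- tibble::tibble(
    record_id = sprintf("r%03d", seq_len(n_disp)),
    resident_id = sample(rid, n_disp, replace = TRUE),
    facility_id = fid,
    dispense_date = ys + sample(-120:370, n_disp, replace = TRUE),
    atc_code = sample(codes, n_disp, replace = TRUE),
    route = sample(c("oral", "oral", "oral", "IV", "IM", "SC", "unknown"),
                   n_disp, replace = TRUE),
    n_packages = sample(1:3, n_disp, replace = TRUE),
    units_per_package = ifelse(runif(n_disp) < 0.2, NA_integer_,
                               sample(c(10L, 14L, 20L, 21L), n_disp,
                                      replace = TRUE)),
    prescriber_id = "g1"
  )
  n_ev <- sample(3:15, 1)
  events <- tibble::tibble(
    resident_id = sample(rid, n_ev, replace = TRUE),
    facility_id = fid,
    event_date = ys + sample(0:364, n_ev, replace = TRUE),
    event_type = sample(c("urine_culture", "flu_vaccine"), n_ev,
                        replace = TRUE)
  )
  claims_dataset(disp, stays, events, year)
}
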