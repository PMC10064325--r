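uti_fixture <- function() {
  stays <- dplyr::bind_rows(
    mk_stay("m1", "2019-01-01", "2019-12-31", sex = "male"),
    mk_stay("w1", "2019-01-01", "2019-12-31", sex = "female"))
  events <- mk_event(c("m1", "w1"), c("2019-03-01", "2019-06-01"))
  list(stays = stays, events = events)
}

test_that("urinary drug-choice ratios link dispensings to cultures within 7 days", {
  fx <- uti_fixture()
  disp <- mk_disp(c("m1", "m1", "w1"),
                  c("2019-03-04", "2019-03-04", "2019-06-02"),
                  c("J01XE01", "J01MA01", "J01XX01"))
  ds <- claims_dataset(disp, fx$stays, fx$events, 2019)
  pi1 <- pi_uti_choice_ratio(ds, "f1", "male")
  expect_equal(pi1$value, 1)          # nitrofurantoin / ofloxacin, day 3
  expect_equal(pi1$indicator_id, "PI1")
  pi2 <- pi_uti_choice_ratio(ds, "f1", "female")
  expect_true(is.na(pi2$value))       # fosfomycin but no linked quinolone
  expect_match(pi2$flags, "zero_denominator")
  expect_error(pi_uti_choice_ratio(ds, "f1", "both"), "male")
})

test_that("dispensings outside the culture window contribute to neither term", {
  fx <- uti_fixture()
  disp <- mk_disp(c("m1", "m1"), c("2019-03-08", "2019-03-09"),
                  c("J01XE01", "J01MA01"))  # day 7 linked, day 8 not
  ds <- claims_dataset(disp, fx$stays, fx$events, 2019)
  pi1 <- pi_uti_choice_ratio(ds, "f1", "male")
  expect_equal(pi1$numerator, 1)
  expect_equal(pi1$denominator, 0)
  # shrinking the window drops the remaining link too
  expect_equal(pi_uti_choice_ratio(ds, "f1", "male", uc_window = 6)$numerator, 0)
})

test_that("repeat quinolones look back 180 days, across the year boundary", {
  stays <- mk_stay("p1", "2018-06-01", "2019-12-31")
  ds <- claims_dataset(
    mk_disp(rep("p1", 2), c("2019-03-01", "2019-05-01"),
            rep("J01MA01", 2)), stays, NULL, 2019)
  pi3 <- pi_repeat_quinolone(ds, "f1")
  expect_equal(pi3$value, 50)  # 61-day gap: second counts, first does not
  expect_match(pi3$flags, "no_lookback_data")

  # 200-day gap exceeds the look-back
  ds2 <- claims_dataset(
    mk_disp(rep("p1", 2), c("2019-01-10", "2019-07-29"), rep("J01MA01", 2)),
    stays, NULL, 2019)
  expect_equal(pi_repeat_quinolone(ds2, "f1")$value, 0)

  # prior-year extract makes a January course a repeat
  ds3 <- claims_dataset(
    mk_disp(rep("p1", 2), c("2018-12-20", "2019-02-05"), rep("J01MA01", 2)),
    stays, NULL, 2019)
  pi3c <- pi_repeat_quinolone(ds3, "f1")
  expect_equal(pi3c$value, 100)
  expect_false(grepl("no_lookback_data", pi3c$flags))
})

test_that("seasonal variation compares cold to hot season counts", {
  stays <- mk_stay("p1", "2019-01-01", "2019-12-31")
  cold_dates <- c(rep("2019-02-01", 8), rep("2019-11-01", 4))
  hot_dates <- rep("2019-07-01", 10)
  disp <- mk_disp(rep("p1", 22), c(cold_dates, hot_dates),
                  rep("J01CA04", 22))
  ds <- claims_dataset(disp, stays, NULL, 2019)
  expect_equal(pi_seasonal_variation(ds, "f1", "ALL_ABX")$value, 20)

  balanced <- mk_disp(rep("p1", 2), c("2019-01-15", "2019-06-15"),
                      rep("J01CR02", 2))
  ds2 <- claims_dataset(balanced, stays, NULL, 2019)
  expect_equal(pi_seasonal_variation(ds2, "f1", "AMC")$value, 0)

  winter_only <- mk_disp("p1", "2019-01-15", "J01CA04")
  ds3 <- claims_dataset(winter_only, stays, NULL, 2019)
  pi4 <- pi_seasonal_variation(ds3, "f1", "ALL_ABX")
  expect_true(is.na(pi4$value))
  expect_match(pi4$flags, "zero_denominator")
  expect_error(pi_seasonal_variation(ds3, "f1", "CEPH"), "ALL_ABX")
})

test_that("first- versus second-line ratio counts the named classes", {
  stays <- mk_stay("p1", "2019-01-01", "2019-12-31")
  disp <- mk_disp(rep("p1", 7), rep("2019-05-01", 7),
                  c("J01CA04", "J01CA04", "J01CA04", "J01CR02", "J01CR02",
                    "J01MA01", "J01DC02"))
  ds <- claims_dataset(disp, stays, NULL, 2019)
  expect_equal(pi_first_vs_second_line(ds, "f1")$value, 2.5)  # 5 / 2

  only_first <- claims_dataset(disp[1:3, ], stays, NULL, 2019)
  expect_true(is.na(pi_first_vs_second_line(only_first, "f1")$value))
})

test_that("prolonged courses use estimated duration strictly above 7 days", {
  stays <- mk_stay("p1", "2019-01-01", "2019-12-31")
  disp <- dplyr::bind_rows(
    mk_disp("p1", "2019-02-01", "J01CA04", n_packages = 1),  # 7.0 days
    mk_disp("p1", "2019-03-01", "J01CA04", n_packages = 2),  # 14 days
    mk_disp("p1", "2019-04-01", "J01MA01", n_packages = 2,
            units = 10)  # quinolone: 20 days but not a monitored drug
  )
  ds <- claims_dataset(disp, stays, NULL, 2019)
  pi7 <- pi_prolonged_courses(ds, "f1")
  expect_equal(pi7$value, 50)  # boundary 7.0-day course is not prolonged
  expect_equal(pi7$denominator, 2)
})

test_that("NSAID co-prescription requires the identical calendar date", {
  stays <- mk_stay("p1", "2019-01-01", "2019-12-31")
  disp <- dplyr::bind_rows(
    mk_disp(rep("p1", 4), c("2019-02-01", "2019-03-01", "2019-04-01",
                            "2019-05-01"), rep("J01CA04", 4)),
    mk_disp("p1", "2019-02-01", "M01AE01"),
    mk_disp("p1", "2019-03-02", "M01AB05")  # one day late: no hit
  )
  ds <- claims_dataset(disp, stays, NULL, 2019)
  expect_equal(pi_nsaid_coprescription(ds, "f1")$value, 25)

  no_nsaid <- claims_dataset(disp[1:4, ], stays, NULL, 2019)
  expect_equal(pi_nsaid_coprescription(no_nsaid, "f1")$value, 0)
})

test_that("flu coverage counts cold-season doses per cold-season resident", {
  stays <- dplyr::bind_rows(lapply(sprintf("p%d", 1:10), function(r) {
    mk_stay(r, "2019-01-01", "2019-12-31")
  }))
  ev <- mk_event(sprintf("p%d", 1:8), rep("2019-11-05", 8),
                 type = "flu_vaccine")
  ds <- claims_dataset(mk_disp("p1", "2019-01-01", "J01CA04")[0, ],
                       stays, ev, 2019)
  expect_equal(pi_flu_coverage(ds, "f1")$value, 80)

  # a hot-season dose does not count; a J07BB dispensing does
  ds2 <- claims_dataset(
    mk_disp("p1", "2019-10-20", "J07BB02"), stays,
    mk_event("p2", "2019-06-01", type = "flu_vaccine"), 2019)
  expect_equal(pi_flu_coverage(ds2, "f1")$numerator, 1)

  # more doses than residents: flagged over-coverage
  ev3 <- mk_event(rep("p1", 11), rep("2019-11-05", 11), type = "flu_vaccine")
  pi9 <- pi_flu_coverage(claims_dataset(ds$dispensings, stays, ev3, 2019),
                         "f1")
  expect_equal(pi9$value, 110)
  expect_match(pi9$flags, "over_coverage")
  expect_equal(pi_flu_coverage(claims_dataset(ds$dispensings, stays, ev3,
                                              2019), "f1",
                               distinct_residents = TRUE)$numerator, 1)
})

test_that("oral cephalosporin share excludes unknown routes", {
  stays <- mk_stay("p1", "2019-01-01", "2019-12-31")
  disp <- mk_disp(rep("p1", 5), rep("2019-05-01", 5),
                  c("J01DC02", "J01DC02", "J01DC02", "J01DD04", "J01DD04"),
                  route = c("oral", "oral", "oral", "IV", "unknown"))
  ds <- claims_dataset(disp, stays, NULL, 2019)
  pi10 <- pi_oral_cephalosporins(ds, "f1")
  expect_equal(pi10$value, 75)
  expect_match(pi10$flags, "route_unknown_excluded:1")

  par_only <- claims_dataset(disp[4, ], stays, NULL, 2019)
  expect_equal(pi_oral_cephalosporins(par_only, "f1")$value, 0)
})

test_that("compliance classification reproduces every target band", {
  # three-band targets
  expect_equal(classify_compliance("PI7", c(4, 4.999, 5, 19.9, 20, 50)),
               c("optimal", "optimal", "acceptable", "acceptable",
                 "non_compliant", "non_compliant"))
  expect_equal(classify_compliance("PI8", c(0, 0.5, 4.999, 5, 12)),
               c("optimal", "acceptable", "acceptable", "non_compliant",
                 "non_compliant"))
  expect_equal(classify_compliance("PI10", c(9.99, 10, 29.9, 30)),
               c("optimal", "acceptable", "acceptable", "non_compliant"))
  expect_equal(classify_compliance("PI1", c(0, 0.1, 0.2, 3)),
               c("optimal", "acceptable", "non_compliant", "non_compliant"))
  expect_equal(classify_compliance("PI3", c(0, 9.99, 10, 40)),
               c("optimal", "acceptable", "non_compliant", "non_compliant"))
  # two-band targets with strict and inclusive bounds
  expect_equal(classify_compliance("PI2", c(1.5, 1.51)),
               c("non_compliant", "optimal"))
  expect_equal(classify_compliance("PI6", c(1.5, 2)),
               c("non_compliant", "optimal"))
  expect_equal(classify_compliance("PI4", c(19.9, 20, 25)),
               c("optimal", "non_compliant", "non_compliant"))
  expect_equal(classify_compliance("PI9", c(89.9, 90, 95)),
               c("non_compliant", "optimal", "optimal"))
  # undefined propagates
  expect_equal(classify_compliance("PI5", NA_real_), "undefined")
  expect_error(classify_compliance("PI99", 1), "no target")
})

test_that("classification is monotone along each target's direction", {
  targets <- pi_targets()
  grades <- c(optimal = 3, acceptable = 2, non_compliant = 1)
  for (id in targets$indicator_id) {
    vals <- sort(c(seq(0, 120, by = 2.5), 1.5, 0.2, 5, 10, 20, 30, 90))
    cls <- grades[classify_compliance(rep(id, length(vals)), vals, targets)]
    dir <- targets$direction[targets$indicator_id == id]
    diffs <- diff(cls)
    if (dir == "lower_better") expect_true(all(diffs <= 0)) else {
      expect_true(all(diffs >= 0))
    }
  }
})

test_that("the full proxy-indicator set is complete and classified", {
  loaded <- demo_dataset()
  pis <- compute_all_pis(loaded$dataset, "f1")
  expect_equal(pis$indicator_id, paste0("PI", 1:10))
  expect_true(all(!is.na(pis$value)))
  expect_true(all(pis$compliance_class %in%
                    c("optimal", "acceptable", "non_compliant")))

  empty <- claims_dataset(loaded$dataset$dispensings[0, ],
                          loaded$dataset$stays[0, ],
                          loaded$dataset$events[0, ], 2019)
  pis0 <- compute_all_pis(empty, "f1")
  expect_equal(nrow(pis0), 10)
  expect_true(all(is.na(pis0$value)))
  expect_true(all(pis0$compliance_class == "undefined"))
})
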