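test_that("resident-days count inclusively and truncate open stays", {
  per <- analysis_period(2019)
  full <- mk_stay("p1", "2019-01-01", "2019-12-31")
  expect_equal(resident_days(full, "f1", per), 365)

  two <- dplyr::bind_rows(mk_stay("p1", "2019-01-01", "2019-01-10"),
                          mk_stay("p2", "2019-01-05", "2019-01-06"))
  expect_equal(resident_days(two, "f1", per), 12)  # 10 + 2, inclusive

  expect_equal(resident_days(mk_stay("p1", "2018-01-01", "2018-12-31"),
                             "f1", per), 0)
  expect_equal(resident_days(mk_stay("p1", "2019-03-01", "2019-03-01"),
                             "f1", per), 1)  # same-day entry/exit
  open <- mk_stay("p1", "2019-07-01", NA)
  expect_equal(resident_days(open, "f1", per), 184)
  # multi-interval period: cold season of a non-leap year
  expect_equal(resident_days(full, "f1", cold_season(2019)), 90 + 92)
})

test_that("residents are counted once regardless of stay length or count", {
  per <- analysis_period(2019)
  stays <- dplyr::bind_rows(
    mk_stay("p1", "2019-01-01", "2019-12-31"),
    mk_stay("p2", "2019-06-01", "2019-06-01"),   # a single day counts
    mk_stay("p3", "2019-01-01", "2019-02-01"),
    mk_stay("p3", "2019-10-01", "2019-12-31"),   # same resident, two stays
    mk_stay("p4", "2018-01-01", "2018-06-01")    # outside the year
  )
  expect_equal(residents_present(stays, "f1", per), 3)
  expect_equal(residents_present(stays[0, ], "f1", per), 0)
})

test_that("rate and share metrics reproduce hand-counted micro-examples", {
  stays <- dplyr::bind_rows(mk_stay("p1", "2019-01-01", "2019-12-31"),
                            mk_stay("p2", "2019-01-01", "2019-12-31"),
                            mk_stay("p3", "2019-01-01", "2019-12-31"),
                            mk_stay("p4", "2019-01-01", "2019-12-31"))
  disp <- mk_disp(c("p1", "p1", "p2"),
                  c("2019-02-01", "2019-03-01", "2019-06-01"),
                  c("J01CA04", "J01CR02", "J01DC02"))
  ds <- claims_dataset(disp, stays[1:2, ], NULL, 2019)
  qm1 <- compute_qm(ds, "f1", "QM1")
  expect_equal(qm1$value, 100 * 3 / 730)
  expect_equal(qm1$numerator, 3)
  expect_equal(qm1$denominator, 730)

  ds4 <- claims_dataset(disp, stays, NULL, 2019)
  expect_equal(compute_qm(ds4, "f1", "QM3")$value, 50)  # 2 of 4 residents

  routes <- mk_disp(rep("p1", 10), rep("2019-05-01", 10), rep("J01CA04", 10),
                    route = c("IV", rep("oral", 9)))
  expect_equal(compute_qm(claims_dataset(routes, stays, NULL, 2019),
                          "f1", "QM12")$value, 10)
})

test_that("unknown routes are excluded from both terms of QM12 and flagged", {
  stays <- mk_stay("p1", "2019-01-01", "2019-12-31")
  disp <- mk_disp(rep("p1", 4), rep("2019-05-01", 4), rep("J01CA04", 4),
                  route = c("IV", "oral", "unknown", "other"))
  qm12 <- compute_qm(claims_dataset(disp, stays, NULL, 2019), "f1", "QM12")
  expect_equal(qm12$numerator, 1)
  expect_equal(qm12$denominator, 2)
  expect_match(qm12$flags, "route_unknown_excluded:2")
})

test_that("DDD metrics exclude uncovered codes with a coverage flag", {
  stays <- mk_stay("p1", "2019-01-01", "2019-12-31")
  disp <- dplyr::bind_rows(
    mk_disp("p1", "2019-02-01", "J01CA04", n_packages = 2),   # 2*14*1/1.5
    mk_disp("p1", "2019-03-01", "J01GB03", record_id = "rx"), # not in ref
    mk_disp("p1", "2019-04-01", "J01CA04", units = NA)        # units unknown
  )
  qm2 <- compute_qm(claims_dataset(disp, stays, NULL, 2019), "f1", "QM2")
  expect_equal(qm2$numerator, 2 * 14 * 1.0 / 1.5)
  expect_match(qm2$flags, "ddd_reference_missing:2")
})

test_that("empty facilities yield 14 undefined, flagged values", {
  ds <- claims_dataset(mk_disp("p1", "2019-01-01", "J01CA04")[0, ],
                       mk_stay("p1", "2019-01-01")[0, ], NULL, 2019)
  all_qm <- compute_all_qms(ds, "f1")
  expect_equal(nrow(all_qm), 14)
  expect_equal(all_qm$indicator_id, paste0("QM", 1:14))
  expect_true(all(is.na(all_qm$value)))
  expect_true(all(grepl("zero_denominator", all_qm$flags)))
})

test_that("duplicate same-day rows count separately unless dedupe is set", {
  stays <- mk_stay("p1", "2019-01-01", "2019-12-31")
  disp <- mk_disp(rep("p1", 2), rep("2019-02-01", 2), rep("J01CA04", 2))
  ds <- claims_dataset(disp, stays, NULL, 2019)
  expect_equal(compute_qm(ds, "f1", "QM1")$numerator, 2)
  expect_equal(compute_qm(ds, "f1", "QM1", dedupe = TRUE)$numerator, 1)
})

test_that("class-count and DDD numerators are additive within J01", {
  for (seed in 1:10) {
    ds <- random_micro_dataset(seed)
    qms <- compute_all_qms(ds, "f1")
    num <- setNames(qms$numerator, qms$indicator_id)
    expect_lte(num["QM4"] + num["QM6"] + num["QM8"] + num["QM10"],
               num["QM1"])
    expect_lte(num["QM5"] + num["QM7"] + num["QM9"] + num["QM11"],
               num["QM2"] + 1e-9)
    shares <- qms$value[qms$indicator_id %in% c("QM3", "QM12", "QM14")]
    shares <- shares[!is.na(shares)]
    expect_true(all(shares >= 0 & shares <= 100))
  }
})

test_that("row order never changes any quantity metric", {
  ds <- random_micro_dataset(99)
  ref <- compute_all_qms(ds, "f1")
  set.seed(1)
  ds2 <- claims_dataset(ds$dispensings[sample(nrow(ds$dispensings)), ],
                        ds$stays[sample(nrow(ds$stays)), ],
                        ds$events[sample(nrow(ds$events)), ], 2019)
  expect_equal(compute_all_qms(ds2, "f1")$value, ref$value)
})

test_that("unknown metric ids and denominator suppression are handled", {
  ds <- random_micro_dataset(3)
  expect_error(compute_qm(ds, "f1", "QM99"), "unknown quantity metric")
  qm1 <- compute_qm(ds, "f1", "QM1", min_denominator = 1e6)
  expect_true(is.na(qm1$value))
  expect_match(qm1$flags, "suppressed_denominator")
})
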