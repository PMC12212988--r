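test_that("mean monthly rainfall averages a half-open window by month count", {
  # constant 1 mm/day over a non-leap year
  s <- toy_rain(constant = 1, from = as.Date("2001-01-01"),
                to = as.Date("2002-12-31"))
  expect_equal(mean_monthly_rain(s, as.Date("2001-01-01"), 12), 365 / 12)

  z <- toy_rain(constant = 0)
  expect_equal(mean_monthly_rain(z, as.Date("1995-01-01"), 12), 0)

  # seeded series vs a day-by-day summation oracle
  r <- toy_rain(seed = 7)
  start <- as.Date("1993-05-01")
  expect_equal(mean_monthly_rain(r, start, 12),
               oracle_rain_sum(r, start, as.Date("1994-05-01")) / 12)
})

test_that("rainfall windows error on coverage gaps unless told days are dry", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2000-12-31"), by = "day")
  gappy <- rain_series(dates[-50], rep(2, length(dates) - 1))
  expect_error(mean_monthly_rain(gappy, as.Date("2000-01-01"), 12),
               "missing")
  expect_equal(mean_monthly_rain(gappy, as.Date("2000-01-01"), 12,
                                 missing = "zero"),
               2 * (length(dates) - 1) / 12)
})

test_that("developmental and adult rainfall use the documented anchors", {
  s <- toy_rain(constant = 1, from = as.Date("1990-01-01"),
                to = as.Date("1994-12-31"))
  # constant series: every 12-month window gives (days in window)/12
  expect_equal(rain_development(s, as.Date("1991-03-01")), 366 / 12) # spans Feb 1992
  expect_equal(rain_adult(s, as.Date("1992-03-01")), 366 / 12)

  # 12-month periodicity: same month-of-year pattern in non-leap years
  dates <- seq(as.Date("2001-01-01"), as.Date("2003-12-31"), by = "day")
  periodic <- rain_series(dates, lubridate::month(dates) * 1.5)
  expect_equal(rain_adult(periodic, as.Date("2002-03-01")),
               rain_adult(periodic, as.Date("2003-03-01")))

  # seeded series vs brute-force oracle
  r <- toy_rain(seed = 11)
  expect_equal(rain_development(r, as.Date("1991-07-04")),
               oracle_rain_sum(r, as.Date("1991-07-04"),
                               as.Date("1992-07-04")) / 12)
})

test_that("rank window means are gap tolerant and match an elementwise oracle", {
  months <- seq(as.Date("1995-01-01"), by = "month", length.out = 12)
  rs <- rank_series(rep("A", 3), months[1:3], c(0.4, 0.5, 0.6))
  expect_equal(rank_window_mean(rs, "A", months[1:3]), 0.5)

  # constant rank with a missing middle month
  rs2 <- rank_series(rep("B", 2), months[c(1, 3)], c(0.9, 0.9))
  expect_equal(rank_window_3mo(rs2, "B", months[2]), 0.9)
  expect_error(rank_window_mean(rs2, "B", months[6:8]), "no rank data")

  set.seed(3)
  vals <- runif(12)
  rs3 <- rank_series(rep("C", 12), months, vals)
  expect_equal(rank_window_mean(rs3, "C", months), mean(vals))
})

test_that("delta construction is exact and rejects mixed units", {
  expect_equal(compute_delta(0.5, 0.5), list(delta = 0, abs_delta = 0))
  expect_equal(compute_delta(0.2, 0.7), list(delta = 0.5, abs_delta = 0.5))
  expect_equal(compute_delta(0.7, 0.2), list(delta = -0.5, abs_delta = 0.5))
  expect_error(compute_delta(0.5, 30, units0 = "rank", units1 = "rain"),
               "unit mismatch")
})

test_that("conception risk set is the cycling-on-day-1 months", {
  rec <- toy_conception_records()
  ranks <- toy_ranks(c("F1", "M1"))
  tab <- build_conception_table(rec, env = "rank", ranks = ranks)
  expect_s3_class(tab, "analysis_table")
  expect_identical(nrow(tab), 6L)          # pregnant months excluded
  expect_identical(sum(tab$outcome), 1)    # one conception
  expect_identical(tab$outcome[tab$event_time == as.Date("1996-06-01")], 1)
  expect_true(all(tab$e0 == 0.5 & tab$e1 == 0.5 & tab$abs_delta == 0))
  expect_true(all(tab$age > 0))
  expect_true(all(tab$group_size == 25))

  # rain environment path on the same records
  rain <- toy_rain(seed = 2)
  tab_rain <- build_conception_table(rec, env = "rain", rain = rain)
  expect_identical(nrow(tab_rain), 6L)
  expect_equal(tab_rain$e0[1], rain_development(rain, as.Date("1990-06-15")))
  expect_equal(tab_rain$e1[tab_rain$event_time == as.Date("1996-03-01")],
               rain_adult(rain, as.Date("1996-03-01")))
})

test_that("live-birth table keeps completed pregnancies and drops censored ones", {
  rec <- toy_livebirth_records()
  ranks <- toy_ranks(all_toy_ids())
  tab <- build_livebirth_table(rec, env = "rank", ranks = ranks)
  expect_identical(nrow(tab), 4L)
  expect_identical(sum(tab$outcome), 3)
  expect_identical(drop_log(tab)$reason, "censored")
  expect_identical(drop_log(tab)$female_id, "F5")
})

test_that("infant-survival table applies the 70-week, censoring and maternal-death rules", {
  rec <- toy_infant_records()
  ranks <- toy_ranks(all_toy_ids())
  tab <- build_infantsurvival_table(rec, env = "rank", ranks = ranks)
  expect_identical(nrow(tab), 4L)
  expect_identical(sum(tab$outcome), 3)
  # the 69-week death is the zero
  expect_identical(tab$outcome[tab$female_id == "F4"], 0)
  dl <- drop_log(tab)
  expect_setequal(dl$reason, c("censored", "maternal_death"))
  expect_identical(dl$female_id[dl$reason == "maternal_death"], "F6")

  # death before birth is a data-integrity error
  bad <- rec
  bad$infants$death_date[1] <- bad$infants$birth_date[1] - 5
  expect_error(repro_records(bad$females, bad$states, bad$pregnancies,
                             bad$infants, bad$census),
               "precedes")
})

test_that("conception builder agrees with a state-walk oracle on random histories", {
  ranks <- toy_ranks(c(paste0("F", 1:5), paste0("M", 1:5)))
  for (seed in c(101, 202, 303)) {
    h <- random_history(seed)
    tab <- build_conception_table(h$records, env = "rank", ranks = ranks)
    expect_identical(nrow(tab), nrow(h$expected_conception))
    merged <- merge(as.data.frame(tab)[c("female_id", "event_time", "outcome")],
                    h$expected_conception,
                    by.x = c("female_id", "event_time"),
                    by.y = c("female_id", "month"))
    expect_identical(nrow(merged), nrow(tab)) # risk sets identical
    expect_equal(merged$outcome.x, merged$outcome.y)
    # no female-month appears twice
    expect_identical(anyDuplicated(tab[c("female_id", "event_time")]), 0L)
  }
})

test_that("analysis records satisfy the arithmetic and range invariants", {
  rec <- toy_conception_records()
  ranks <- toy_ranks(c("F1", "M1"))
  tab <- build_conception_table(rec, env = "rank", ranks = ranks)
  expect_true(all(tab$e0 + tab$delta == tab$e1))
  expect_true(all(tab$abs_delta == abs(tab$delta)))
  expect_true(all(tab$e0 >= 0 & tab$e0 <= 1 & tab$abs_delta <= 1))
  # round trip through CSV preserves records and kinds
  path <- withr::local_tempfile(fileext = ".csv")
  write_analysis_table(tab, path)
  back <- read_analysis_table(path)
  expect_identical(outcome_kind(back), "conception")
  expect_identical(environment_kind(back), "rank")
  expect_equal(back$e0, tab$e0)
  expect_equal(back$outcome, tab$outcome)
})

test_that("missing environment data drops records with logged reasons", {
  rec <- toy_conception_records()
  # ranks only for the subject, not the mother: e0 unavailable
  ranks <- toy_ranks("F1")
  tab <- build_conception_table(rec, env = "rank", ranks = ranks)
  expect_identical(nrow(tab), 0L)
  expect_true(all(drop_log(tab)$reason == "missing_rank_window"))
  expect_identical(nrow(drop_log(tab)), 6L)
})

test_that("schema validation reports violations instead of stopping", {
  bad_rain <- data.frame(date = c("2000-01-02", "2000-01-01"),
                         rain_mm = c(1, -2))
  bad_ranks <- data.frame(female_id = c("A", "A"),
                          year_month = c("2000-01", "2000-01"),
                          rank = c(0.5, 1.4))
  v <- validate_inputs(rain = bad_rain, ranks = bad_ranks)
  expect_true(nrow(v) >= 3)
  expect_setequal(unique(v$table), c("rain", "ranks"))
  ok <- validate_inputs(rain = data.frame(date = c("2000-01-01", "2000-01-02"),
                                          rain_mm = c(0, 1)))
  expect_identical(nrow(ok), 0L)
})

test_that("typed long-format events round-trip into structured records", {
  events <- data.frame(
    female_id = c("F1", "F1", "F1", "F1", "F1", "F1"),
    record_type = c("female_birth", "state", "state", "conception",
                    "pregnancy_end", "infant_birth"),
    date = c("1990-06-15", "1996-01-01", "1996-02-01", "1996-01-20",
             "1996-08-10", "1996-08-10"),
    value = c("M1", "cycling", "pregnant", "", "live", "I1"),
    group_id = c("", "G1", "G1", "", "", ""))
  census <- data.frame(group_id = "G1", year_month = c("1996-01", "1996-02"),
                       size = 25)
  rec <- read_repro_events(events, census)
  expect_s3_class(rec, "repro_records")
  expect_identical(nrow(rec$pregnancies), 1L)
  expect_true(rec$pregnancies$live)
  expect_identical(rec$infants$infant_id, "I1")

  # pregnancy end with no preceding conception is an integrity error
  bad <- events[events$record_type != "conception", ]
  expect_error(read_repro_events(bad, census), "without a conception")
})
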