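test_that("midnight splitting conserves duration and respects dates", {
  b <- mk_bouts(T0 + MS_DAY - 10 * MS_MIN, T0 + MS_DAY + 10 * MS_MIN)
  sp <- split_at_midnight(b)
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$end_ms - sp$start_ms, rep(10 * MS_MIN, 2))
  expect_equal(as.integer(diff(floor(sp$start_ms / MS_DAY))), 1L)

  within <- mk_bouts(T0 + MS_HOUR, T0 + 2 * MS_HOUR)
  expect_equal(split_at_midnight(within), within)

  withr::local_seed(17)
  for (rep in 1:20) {
    b <- random_bout_set()
    sp <- split_at_midnight(b)
    expect_equal(sum(sp$end_ms - sp$start_ms),
                 sum(b$end_ms - b$start_ms))
    expect_true(all(floor(sp$start_ms / MS_DAY) ==
                      floor((sp$end_ms - 1) / MS_DAY)))
  }
})

test_that("daily measures follow their defining arithmetic", {
  day <- data.frame(date = as.Date("2021-10-01"), valid = TRUE)
  b <- mk_bouts(T0 + c(10 * MS_HOUR, 20 * MS_HOUR),
                T0 + c(10.5 * MS_HOUR, 20 * MS_HOUR + 10 * MS_MIN))
  dm <- daily_measures(b, day)
  expect_equal(dm$total_on_minutes, 40)
  expect_equal(dm$on_bout_count, 2L)
  expect_equal(dm$mean_on_bout_minutes, 20)
  expect_equal(dm$mean_off_bout_minutes, 570)
  expect_equal(dm$log_on_bout_count, log(2))

  single <- mk_bouts(T0 + 10 * MS_HOUR, T0 + 10.5 * MS_HOUR)
  dm1 <- daily_measures(single, day)
  expect_equal(dm1$total_on_minutes, 30)
  expect_equal(dm1$mean_on_bout_minutes, 30)
  expect_true(is.na(dm1$mean_off_bout_minutes))

  # a valid day without bouts still appears, with zero volume
  dm0 <- daily_measures(mk_bouts(numeric(0), numeric(0)), day)
  expect_equal(dm0$total_on_minutes, 0)
  expect_true(is.na(dm0$log_on_bout_count))

  # ln(count): 55 fragments
  many <- mk_bouts(T0 + (1:55) * 10 * MS_MIN + (0:54) * MS_MIN,
                   T0 + (1:55) * 10 * MS_MIN + (1:55) * MS_MIN)
  expect_equal(daily_measures(many, day)$log_on_bout_count, log(55),
               tolerance = 1e-12)

  # unsplit bouts are a contract violation
  cross <- mk_bouts(T0 + MS_DAY - MS_MIN, T0 + MS_DAY + MS_MIN)
  expect_error(daily_measures(cross, day), "split at midnight")
})

test_that("only valid days are emitted", {
  days <- data.frame(date = as.Date("2021-10-01") + 0:1,
                     valid = c(TRUE, FALSE))
  b <- mk_bouts(c(T0 + MS_HOUR, T0 + MS_DAY + MS_HOUR),
                c(T0 + 2 * MS_HOUR, T0 + MS_DAY + 2 * MS_HOUR))
  dm <- daily_measures(b, days)
  expect_equal(nrow(dm), 1L)
  expect_equal(dm$date, as.Date("2021-10-01"))
})

test_that("minute grid distributes bout seconds across minutes", {
  b <- mk_bouts(T0 + 36030000, T0 + 36135000)   # 10:00:30 -> 10:02:15
  g <- minute_grid(b, span = rep(as.Date("2021-10-01"), 2))
  got <- g$on_seconds[g$minute %in% c(600, 601, 602)]
  expect_equal(got, c(30, 60, 15))
  expect_equal(g$binary_on[g$minute %in% c(599, 600, 603)], c(0, 1, 0))
  expect_equal(sum(g$on_seconds), 105)

  empty <- minute_grid(mk_bouts(numeric(0), numeric(0)),
                       span = rep(as.Date("2021-10-01"), 2))
  expect_equal(sum(empty$on_seconds), 0)
  expect_equal(nrow(empty), 1440L)
})

test_that("grid, split and daily measures agree on totals", {
  withr::local_seed(23)
  for (rep in 1:20) {
    b <- random_bout_set()
    g <- minute_grid(b, span = c(as.Date("2021-10-01"),
                                 as.Date("2021-10-01") + 3))
    expect_equal(sum(g$on_seconds), sum(b$end_ms - b$start_ms) / 1000,
                 tolerance = 1e-9)
    sp <- split_at_midnight(b)
    days <- data.frame(date = as.Date("2021-10-01") + 0:3, valid = TRUE)
    dm <- daily_measures(sp, days)
    # per-day minute seconds match 60 x daily totals
    per_day <- tapply(g$on_seconds, as.character(g$date), sum)
    expect_equal(as.numeric(per_day[as.character(dm$date)]),
                 60 * dm$total_on_minutes, tolerance = 1e-9)
    # mean on-bout x count recovers the total
    has <- dm$on_bout_count >= 1L
    expect_equal(dm$mean_on_bout_minutes[has] * dm$on_bout_count[has],
                 dm$total_on_minutes[has], tolerance = 1e-9)
  }
})

test_that("cohort summaries reduce to the data in degenerate cases", {
  dates <- as.Date("2021-10-01") + 0:9
  flat <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(participant_id = paste0("p", i), date = dates,
               total_on_minutes = 200)
  }))
  cs <- cohort_daily_summary(flat)
  expect_true(all(cs$median == 200))
  expect_true(all(cs$sm_p10 == 200 & cs$sm_p90 == 200))

  one <- data.frame(participant_id = "p1", date = dates,
                    total_on_minutes = 1:10 * 10)
  cs1 <- cohort_daily_summary(one)
  expect_equal(cs1$median, cs1$p90)
  expect_equal(cs1$median, 1:10 * 10)
})

test_that("a step change crosses its midpoint within 3 days when smoothed", {
  k <- 20
  dates <- as.Date("2021-10-01") + 0:39
  val <- c(rep(100, k), rep(300, 40 - k))
  m <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(participant_id = paste0("p", i), date = dates,
               total_on_minutes = val)
  }))
  cs <- cohort_daily_summary(m)
  cross <- min(cs$rel_day[cs$sm_median >= 200])
  expect_lte(abs(cross - k), 3)
})
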