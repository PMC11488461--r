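test_that("simulation is deterministic in (params, seed)", {
  p <- sim_params("android", n_days = 3, seed = 9)
  a <- simulate_participant(p)
  b <- simulate_participant(p)
  expect_equal(a$stream$records, b$stream$records)
  expect_equal(a$truth_bouts, b$truth_bouts)
  p2 <- sim_params("android", n_days = 3, seed = 10)
  expect_false(identical(simulate_participant(p2)$stream$records,
                         a$stream$records))
  # simulation must not disturb the caller's RNG stream
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(simulate_participant(p)); after <- stats::runif(1)
  expect_equal(before, after)
})

test_that("degenerate rates produce empty, invalid streams", {
  p <- sim_params("android", n_days = 3, seed = 2,
                  bout_rate_per_wake_hour = 0,
                  notification_wake_rate_per_hour = 0)
  out <- simulate_participant(p)
  expect_equal(nrow(out$stream$records), 0L)
  expect_false(any(out$truth_valid_days$valid))
})

test_that("truth bout counts follow the Poisson intensity", {
  p <- sim_params("android", n_days = 30, seed = 13,
                  bout_rate_per_wake_hour = 3,
                  bout_duration_meanlog = log(30),
                  bout_duration_sdlog = 0.3,
                  notification_wake_rate_per_hour = 0)
  out <- simulate_participant(p)
  # 3 per wake hour x 16 wake hours x 30 days = 1440 expected; short
  # durations keep thinning losses negligible, so 3 sigma ~ 114
  expect_lt(abs(nrow(out$truth_bouts) - 1440), 114)
  expect_true(all(diff(out$truth_bouts$start_ms) >= 0))
  # non-overlap of truth bouts
  tb <- out$truth_bouts
  expect_true(all(tb$start_ms[-1L] >= tb$end_ms[-nrow(tb)]))
})

test_that("steady battery drain keeps every iOS day valid", {
  p <- sim_params("ios", n_days = 10, seed = 4,
                  battery_drain_pct_per_hour = 5)
  out <- simulate_participant(p)
  expect_true(all(out$truth_valid_days$valid))
})

test_that("dropout deletes events but not the ground truth", {
  p <- sim_params("ios", n_days = 5, seed = 6)
  out <- simulate_participant(p)
  expect_equal(inject_dropout(out, list())$stream$records,
               out$stream$records)
  # a whole-day blackout invalidates that day under the battery heuristic
  day3 <- date_to_ms(as.Date("2021-10-03"))
  dropped <- inject_dropout(out, list(c(day3, day3 + MS_DAY)))
  expect_equal(dropped$truth_bouts, out$truth_bouts)
  vm <- ios_valid_minutes(dropped$stream,
                          span = range(out$truth_valid_days$date))
  vd <- ios_valid_days(vm)
  expect_false(vd$valid[vd$date == as.Date("2021-10-03")])
  expect_true(vd$valid[vd$date == as.Date("2021-10-05")])
})

test_that("deleting a close event is healed by imputation plus cap", {
  p <- sim_params("android", n_days = 2, seed = 8,
                  notification_wake_rate_per_hour = 0)
  out <- simulate_participant(p)
  tb <- out$truth_bouts
  # drop exactly one screen_off event in the middle of the stream
  victim <- tb$end_ms[floor(nrow(tb) / 2)]
  dropped <- inject_dropout(out, list(c(victim, victim + 1)))
  b <- extract_bouts(dropped$stream,
                     extraction_config("default",
                                       notification_min_seconds = 0))
  i <- which(b$start_ms == tb$start_ms[floor(nrow(tb) / 2)])
  expect_length(i, 1L)
  expect_true(b$close_imputed[i] || b$capped[i])
  # its end is the next open, or start + cap, whichever came first
  nxt <- tb$start_ms[floor(nrow(tb) / 2) + 1L]
  expect_equal(b$end_ms[i], min(nxt, b$start_ms[i] + 30 * MS_MIN))
})

test_that("screen-time error grows with the dropped-event fraction", {
  p <- sim_params("android", n_days = 10, seed = 14,
                  notification_wake_rate_per_hour = 0,
                  bout_duration_meanlog = log(150),
                  bout_duration_sdlog = 0.5)
  out <- simulate_participant(p)
  truth_total <- sum(out$truth_bouts$end_ms - out$truth_bouts$start_ms)
  # delete all events in the first k hours of each day
  err_at <- vapply(c(0, 4, 8), function(k) {
    if (k == 0) {
      d <- out
    } else {
      wins <- lapply(0:9, function(day) {
        c(T0 + day * MS_DAY + 12 * MS_HOUR,
          T0 + day * MS_DAY + (12 + k) * MS_HOUR)
      })
      d <- inject_dropout(out, wins)
    }
    b <- extract_bouts(d$stream, extraction_config("default"))
    abs(sum(b$end_ms - b$start_ms) - truth_total)
  }, numeric(1))
  expect_true(all(diff(err_at) >= 0))
  expect_equal(err_at[1], 0)
})

test_that("cohort generation shifts sleep schedules deterministically", {
  base <- sim_params("android", n_days = 6, seed = 3,
                     notification_wake_rate_per_hour = 0)
  trans <- date_to_ms(as.Date("2021-10-04")) + 7 * MS_HOUR
  coh1 <- simulate_dst_cohort(3, base, -60, trans)
  coh2 <- simulate_dst_cohort(3, base, -60, trans)
  expect_equal(lapply(coh1, function(o) o$stream$records),
               lapply(coh2, function(o) o$stream$records))
  expect_equal(vapply(coh1, function(o) o$stream$participant_id, ""),
               c("sim-001", "sim-002", "sim-003"))
  # participants differ from one another
  expect_false(identical(coh1[[1]]$stream$records,
                         coh1[[2]]$stream$records))
})
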