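#' Simulation parameters for synthetic phone-state logs
#'
#' Defines one synthetic participant: a sleep/wake schedule in a fixed
#' local clock (UTC plus `tz_offset_hours`; full time-zone-database
#' semantics are intentionally avoided so the clock model stays
#' transparent), screen-on bouts started as a Poisson process during wake
#' hours with lognormal durations, iOS battery dynamics emitting an event
#' at every integer-percent crossing, Android notification screen-wakes,
#' optional log-dropout windows, and an optional sleep-schedule shift
#' after a clock-change instant.
#'
#' Defaults emulate the daily screen-time levels typical of naturalistic
#' adult/adolescent cohorts: 16 wake hours with 4 bout starts per wake
#' hour and a lognormal duration with `meanlog = 4.55`, `sdlog = 1.4`
#' (log-seconds) give roughly 60 bouts and 4--4.5 hours of screen time
#' per day, with about the 97th duration percentile near 30 minutes.
#'
#' @param os `"ios"` or `"android"`.
#' @param n_days Number of simulated days.
#' @param start_date First simulated UTC date.
#' @param sleep_start_local,sleep_end_local Sleep onset/offset as local
#'   minute-of-day (defaults 23:00 and 07:00; the interval may wrap
#'   midnight).
#' @param tz_offset_hours Fixed local-clock offset from UTC in hours
#'   (default -5, US Eastern standard time).
#' @param bout_rate_per_wake_hour Poisson rate of bout starts per wake
#'   hour.
#' @param bout_duration_meanlog,bout_duration_sdlog Lognormal duration
#'   parameters, log-seconds.
#' @param battery_drain_pct_per_hour iOS battery drain rate while awake.
#' @param battery_charge_pct_per_hour iOS charging rate.
#' @param charge_sessions_per_day iOS: `> 0` means the phone is plugged
#'   in at each day's sleep onset and charged to 100%; `0` means it
#'   drains continuously to empty.
#' @param notification_wake_rate_per_hour Android: Poisson rate of brief
#'   notification screen-wakes (arriving around the clock).
#' @param notification_wake_seconds Duration of each notification wake.
#' @param dropout_windows Optional list of `c(start_ms, end_ms)` windows
#'   in which all log events are deleted (see [inject_dropout()]).
#' @param dst_sleep_shift_minutes Shift (minutes, may be negative) added
#'   to the sleep schedule on days starting after `dst_transition_ms`.
#' @param dst_transition_ms Epoch ms of the clock-change instant, or
#'   `NULL` for none.
#' @param seed Integer RNG seed; identical parameters give identical
#'   output.
#' @param participant_id Identifier for the generated stream.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(os = c("ios", "android"), n_days = 30,
                       start_date = as.Date("2021-10-01"),
                       sleep_start_local = 23 * 60,
                       sleep_end_local = 7 * 60,
                       tz_offset_hours = -5,
                       bout_rate_per_wake_hour = 4,
                       bout_duration_meanlog = 4.55,
                       bout_duration_sdlog = 1.4,
                       battery_drain_pct_per_hour = 5,
                       battery_charge_pct_per_hour = 30,
                       charge_sessions_per_day = 1,
                       notification_wake_rate_per_hour = 2,
                       notification_wake_seconds = 3,
                       dropout_windows = NULL,
                       dst_sleep_shift_minutes = 0,
                       dst_transition_ms = NULL,
                       seed = 1, participant_id = "sim-01") {
  os <- match.arg(os)
  stopifnot(n_days >= 1, bout_rate_per_wake_hour >= 0,
            bout_duration_sdlog >= 0, battery_drain_pct_per_hour > 0,
            battery_charge_pct_per_hour > 0,
            notification_wake_rate_per_hour >= 0,
            notification_wake_seconds > 0)
  if (sleep_start_local == sleep_end_local) {
    stop("sleep interval must be non-degenerate")
  }
  structure(as.list(environment()), class = "sim_params")
}

# Wake intervals in UTC ms for each simulated day, honouring the
# post-transition sleep shift. Sleep [ss, se) in local minutes (wrapping
# allowed); wake is its complement, taken as one interval per day from
# sleep offset to the next sleep onset.
.wake_intervals <- function(p) {
  t0 <- date_to_ms(p$start_date)
  off_ms <- p$tz_offset_hours * MS_PER_HOUR
  out <- vector("list", p$n_days)
  for (d in seq_len(p$n_days) - 1L) {
    ss <- p$sleep_start_local
    se <- p$sleep_end_local
    # wake runs [se, ss) local; if ss < se the wake period wraps local
    # midnight, handled by extending onset into the next local day
    onset <- if (ss > se) ss else ss + 1440
    a_local <- d * 1440 + se
    b_local <- d * 1440 + onset
    a <- t0 + a_local * MS_PER_MIN - off_ms
    b <- t0 + b_local * MS_PER_MIN - off_ms
    if (!is.null(p$dst_transition_ms) && a >= p$dst_transition_ms) {
      sh <- p$dst_sleep_shift_minutes * MS_PER_MIN
      a <- a + sh
      b <- b + sh
    }
    out[[d + 1L]] <- c(a, b)
  }
  out
}

#' Simulate one participant's phone-state log with ground truth
#'
#' Draws screen-on bout starts as a Poisson process over the wake
#' intervals with lognormal durations; starts falling inside an active
#' bout are discarded (thinning), so the truth bouts are non-overlapping
#' by construction. For iOS, battery level follows a piecewise-linear
#' drain/charge trajectory and an event is emitted at every
#' integer-percent crossing; for Android, notification screen-wakes of
#' fixed short duration are added (and flagged in the truth). The events
#' are then serialised into an [event_stream()].
#'
#' @param params A [sim_params()].
#' @return A list of class `sim_output` with elements `stream` (an
#'   [event_stream()]), `truth_bouts` (bout frame with a `notification`
#'   flag column), `truth_valid_days` (data frame `date`, `valid`), and
#'   `params`.
#' @export
simulate_participant <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    wake <- .wake_intervals(p)
    span_start <- date_to_ms(p$start_date)
    span_end <- span_start + p$n_days * MS_PER_DAY

    # candidate use bouts: Poisson starts per wake interval
    starts <- numeric(0)
    for (iv in wake) {
      len_h <- (iv[2] - iv[1]) / MS_PER_HOUR
      n <- stats::rpois(1, p$bout_rate_per_wake_hour * len_h)
      if (n > 0) starts <- c(starts, sort(stats::runif(n, iv[1], iv[2])))
    }
    durs <- stats::rlnorm(length(starts), p$bout_duration_meanlog,
                          p$bout_duration_sdlog) * MS_PER_SEC
    cand <- data.frame(start_ms = starts, end_ms = starts + durs,
                       notification = rep(FALSE, length(starts)))

    # notification wakes (Android): arrive around the clock
    if (p$os == "android" && p$notification_wake_rate_per_hour > 0) {
      total_h <- p$n_days * 24
      n <- stats::rpois(1, p$notification_wake_rate_per_hour * total_h)
      if (n > 0) {
        ns <- sort(stats::runif(n, span_start, span_end))
        cand <- rbind(cand, data.frame(
          start_ms = ns,
          end_ms = ns + p$notification_wake_seconds * MS_PER_SEC,
          notification = TRUE))
      }
    }
    cand <- cand[order(cand$start_ms), , drop = FALSE]

    # thinning: discard any start inside an active bout
    keep <- logical(nrow(cand))
    cur_end <- -Inf
    for (i in seq_len(nrow(cand))) {
      if (cand$start_ms[i] >= cur_end) {
        keep[i] <- TRUE
        cur_end <- cand$end_ms[i]
      }
    }
    truth <- cand[keep, , drop = FALSE]
    truth <- truth[truth$end_ms <= span_end, , drop = FALSE]  # clip tail
    rownames(truth) <- NULL
    truth_bouts <- data.frame(start_ms = round(truth$start_ms),
                              end_ms = round(truth$end_ms),
                              close_imputed = rep(FALSE, nrow(truth)),
                              capped = rep(FALSE, nrow(truth)),
                              notification = truth$notification)
    truth_bouts <- truth_bouts[
      truth_bouts$end_ms > truth_bouts$start_ms, , drop = FALSE]

    # screen events
    open_kind <- if (p$os == "ios") "unlocked" else "screen_on"
    close_kind <- if (p$os == "ios") "locked" else "screen_off"
    ev <- data.frame(
      timestamp_ms = as.numeric(rbind(truth_bouts$start_ms,
                                      truth_bouts$end_ms)),
      kind = rep(c(open_kind, close_kind), nrow(truth_bouts)),
      battery_level = rep(NA_integer_, 2L * nrow(truth_bouts))
    )

    if (p$os == "ios") {
      batt <- .battery_events(p, wake, span_start, span_end)
      ev <- rbind(ev, batt)
    }
    stream <- event_stream(p$participant_id, p$os, ev)

    days <- p$start_date + seq_len(p$n_days) - 1L
    truth_valid_days <- if (p$os == "ios") {
      vm <- ios_valid_minutes(stream, span = range(days))
      vd <- ios_valid_days(vm)
      data.frame(date = vd$date, valid = vd$valid)
    } else {
      vd <- android_valid_days(truth_bouts, span = range(days))
      data.frame(date = vd$date, valid = vd$valid)
    }

    out <- structure(list(stream = stream, truth_bouts = truth_bouts,
                          truth_valid_days = truth_valid_days,
                          params = p),
                     class = "sim_output")
    if (!is.null(p$dropout_windows)) {
      out <- inject_dropout(out, p$dropout_windows)
    }
    out
  })
}

# Piecewise-linear battery trajectory: full at each day's wake start,
# draining while awake, plugged in at sleep onset and charged back to
# 100% (then flat) when charge_sessions_per_day > 0; continuous drain to
# empty otherwise. Emits one event per integer-percent crossing.
.battery_events <- function(p, wake, span_start, span_end) {
  segs <- list()   # each: c(t_a, t_b, l_a, l_b)
  init <- NULL
  if (p$charge_sessions_per_day > 0) {
    # plugged in (full) before the first wake period begins
    init <- data.frame(timestamp_ms = span_start, kind = "battery",
                       battery_level = 100L)
    for (iv in wake) {
      empty_ms <- iv[1] + 100 / p$battery_drain_pct_per_hour * MS_PER_HOUR
      if (empty_ms < iv[2]) {          # battery dies before sleep onset
        segs <- c(segs, list(c(iv[1], empty_ms, 100, 0)))
        drain_end_level <- 0
      } else {
        drain_end_level <- 100 - p$battery_drain_pct_per_hour *
          (iv[2] - iv[1]) / MS_PER_HOUR
        segs <- c(segs, list(c(iv[1], iv[2], 100, drain_end_level)))
      }
      charge_ms <- (100 - drain_end_level) /
        p$battery_charge_pct_per_hour * MS_PER_HOUR
      segs <- c(segs, list(c(iv[2], iv[2] + charge_ms,
                             drain_end_level, 100)))
    }
  } else {
    empty_ms <- span_start + 100 / p$battery_drain_pct_per_hour *
      MS_PER_HOUR
    segs <- list(c(span_start, min(empty_ms, span_end), 100,
                   max(0, 100 - p$battery_drain_pct_per_hour *
                         (min(empty_ms, span_end) - span_start) /
                         MS_PER_HOUR)))
  }
  ts <- numeric(0)
  lv <- integer(0)
  for (sg in segs) {
    t_a <- sg[1]; t_b <- sg[2]; l_a <- sg[3]; l_b <- sg[4]
    if (t_b <= t_a) next
    if (l_b < l_a) {
      levels <- seq(floor(l_a), ceiling(l_b), by = -1)
      levels <- levels[levels <= l_a & levels >= l_b]
    } else {
      levels <- seq(ceiling(l_a), floor(l_b), by = 1)
      levels <- levels[levels >= l_a & levels <= l_b]
    }
    if (!length(levels)) next
    tt <- t_a + (levels - l_a) / (l_b - l_a) * (t_b - t_a)
    ok <- tt >= span_start & tt < span_end
    ts <- c(ts, round(tt[ok]))
    lv <- c(lv, as.integer(levels[ok]))
  }
  out <- data.frame(timestamp_ms = ts, kind = "battery",
                    battery_level = lv)
  if (!is.null(init)) out <- rbind(init, out)
  out
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(
    "<sim_output> %s (%s): %d truth bouts, %d events, %d/%d valid days\n",
    x$params$participant_id, x$params$os, nrow(x$truth_bouts),
    nrow(x$stream$records), sum(x$truth_valid_days$valid),
    nrow(x$truth_valid_days)))
  invisible(x)
}

#' Delete log events inside dropout windows
#'
#' Emulates sensor noncollection: every event with a timestamp inside any
#' half-open window `[start_ms, end_ms)` is removed from the stream. The
#' ground truth is left untouched so recovery can be scored against it.
#'
#' @param output A `sim_output` from [simulate_participant()].
#' @param windows List of numeric `c(start_ms, end_ms)` pairs (or a
#'   two-column matrix).
#' @return The modified `sim_output`; attribute `n_dropped` on the stream
#'   records how many events were deleted.
#' @export
inject_dropout <- function(output, windows) {
  stopifnot(inherits(output, "sim_output"))
  if (is.matrix(windows)) {
    windows <- lapply(seq_len(nrow(windows)), function(i) windows[i, ])
  }
  rec <- output$stream$records
  drop <- rep(FALSE, nrow(rec))
  for (w in windows) {
    stopifnot(length(w) == 2, w[2] >= w[1])
    drop <- drop | (rec$timestamp_ms >= w[1] & rec$timestamp_ms < w[2])
  }
  stream <- event_stream(output$stream$participant_id, output$stream$os,
                         rec[!drop, , drop = FALSE])
  attr(stream, "n_dropped") <- sum(drop)
  output$stream <- stream
  output
}

#' Simulate a cohort straddling a clock change
#'
#' Generates `n_participants` independent participants whose sleep
#' schedules shift by `shift_minutes` on days after
#' `transition_ms` — the natural experiment a daylight-saving transition
#' creates. Per-participant seeds are derived deterministically from the
#' base seed, so the whole cohort is reproducible.
#'
#' @param n_participants Number of participants (>= 2).
#' @param base A [sim_params()] used as the template (its `seed` is the
#'   master seed).
#' @param shift_minutes Post-transition sleep shift in minutes (negative
#'   = sleep earlier).
#' @param transition_ms Epoch ms of the clock-change instant.
#' @return A list of `sim_output`, one per participant.
#' @export
simulate_dst_cohort <- function(n_participants, base, shift_minutes,
                                transition_ms) {
  stopifnot(inherits(base, "sim_params"), n_participants >= 2)
  lapply(seq_len(n_participants), function(i) {
    p <- base
    p$participant_id <- sprintf("sim-%03d", i)
    p$seed <- (base$seed + 7919L * i) %% .Machine$integer.max
    p$dst_sleep_shift_minutes <- shift_minutes
    p$dst_transition_ms <- transition_ms
    simulate_participant(p)
  })
}
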