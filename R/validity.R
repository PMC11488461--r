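#' Label valid monitoring minutes for an iOS stream
#'
#' iOS logs include a battery event for every 1% change in charge level,
#' so battery telemetry doubles as a liveness signal for the logging app.
#' A UTC minute is labelled valid when either
#' \enumerate{
#'   \item it overlaps a gap of at most 60 minutes between consecutive
#'     battery events (each event marks a 1% change, so such a gap implies
#'     the level was changing at >= 1% per hour), or
#'   \item it falls within 12 hours after a battery event at 100% with no
#'     intervening battery event — the phone was charged to full and
#'     plausibly still plugged in. The window ends early at the first
#'     subsequent battery event (a level drop signals discharging has
#'     resumed, re-enabling criterion 1); a repeated 100% reading restarts
#'     it.
#' }
#' Minutes use the half-open convention `[t, t + 60 s)`; the minute
#' containing a qualifying battery event is valid.
#'
#' @param stream An iOS [event_stream()].
#' @param span Optional `Date` vector of length 2 giving the first and
#'   last UTC date to label; defaults to the dates spanned by the stream's
#'   events.
#' @return A data frame with one row per minute of each day in the span:
#'   `date`, `minute` (0--1439), `valid` (logical).
#' @export
ios_valid_minutes <- function(stream, span = NULL) {
  stopifnot(inherits(stream, "event_stream"))
  if (stream$os != "ios") {
    stop("valid-minute labelling is defined for iOS streams only")
  }
  rec <- stream$records
  if (is.null(span)) {
    if (nrow(rec) == 0L) stop("empty stream and no span given")
    span <- range(ms_to_date(rec$timestamp_ms))
  }
  span <- as.Date(span)
  day0 <- span[1]
  n_days <- as.integer(span[2] - span[1]) + 1L
  n_min <- n_days * 1440L
  origin_ms <- date_to_ms(day0)
  valid <- logical(n_min)

  batt <- rec[rec$kind == "battery", , drop = FALSE]
  mark <- function(lo_ms, hi_ms) {
    # mark minutes overlapping [lo_ms, hi_ms]; hi inclusive at minute level
    lo <- floor((lo_ms - origin_ms) / MS_PER_MIN) + 1L
    hi <- floor((hi_ms - origin_ms) / MS_PER_MIN) + 1L
    lo <- max(lo, 1L); hi <- min(hi, n_min)
    if (lo <= hi) valid[lo:hi] <<- TRUE
  }
  if (nrow(batt) >= 2L) {
    ts <- batt$timestamp_ms
    gap_ok <- diff(ts) <= 60 * MS_PER_MIN
    for (i in which(gap_ok)) mark(ts[i], ts[i + 1L])
  }
  if (nrow(batt) >= 1L) {
    ts <- batt$timestamp_ms
    full <- which(batt$battery_level == 100L)
    for (i in full) {
      w_end <- ts[i] + 12 * MS_PER_HOUR
      if (i < nrow(batt)) w_end <- min(w_end, ts[i + 1L])
      # half-open [t, w_end): last valid minute is the one containing
      # w_end - 1 ms
      if (w_end > ts[i]) mark(ts[i], w_end - 1)
    }
  }
  data.frame(
    date = rep(day0 + seq_len(n_days) - 1L, each = 1440L),
    minute = rep.int(0:1439, n_days),
    valid = valid
  )
}

#' Aggregate iOS valid minutes into valid days
#'
#' A day is valid when it has at least 1080 valid minutes (18 hours).
#'
#' @param minutes Data frame from [ios_valid_minutes()].
#' @param min_valid_minutes Threshold, default 1080.
#' @return A data frame `date`, `valid_minutes`, `valid`.
#' @export
ios_valid_days <- function(minutes, min_valid_minutes = 1080) {
  stopifnot(all(c("date", "minute", "valid") %in% names(minutes)))
  agg <- stats::aggregate(valid ~ date, data = minutes, FUN = sum)
  names(agg)[2] <- "valid_minutes"
  agg$valid <- agg$valid_minutes >= min_valid_minutes
  agg[order(agg$date), ]
}

#' Label valid monitoring days for Android from screen-on bouts
#'
#' Android logs carry no battery telemetry, so minute-level validity is
#' undefined; instead a day is labelled valid when at least
#' `min_distinct_hours` distinct clock hours (0--23, UTC) contain at least
#' one screen-on bout. A bout spanning an hour boundary counts toward
#' every hour it overlaps.
#'
#' @param bouts Sorted bout data frame (finite ends).
#' @param span Optional `Date` length-2 range of days to label; defaults
#'   to the dates spanned by the bouts.
#' @param min_distinct_hours Threshold, default 8.
#' @return A data frame `date`, `distinct_hours`, `valid`.
#' @export
android_valid_days <- function(bouts, span = NULL, min_distinct_hours = 8) {
  .check_bouts(bouts)
  if (any(is.na(bouts$end_ms))) stop("bouts must have resolved ends")
  if (is.null(span)) {
    if (nrow(bouts) == 0L) stop("no bouts and no span given")
    span <- c(ms_to_date(min(bouts$start_ms)),
              ms_to_date(max(bouts$end_ms - 1)))
  }
  span <- as.Date(span)
  days <- seq(span[1], span[2], by = "day")
  hours_hit <- integer(0)
  if (nrow(bouts)) {
    h1 <- floor(bouts$start_ms / MS_PER_HOUR)
    h2 <- floor((bouts$end_ms - 1) / MS_PER_HOUR)   # end exclusive
    hours_hit <- unique(unlist(mapply(seq, h1, h2, SIMPLIFY = FALSE)))
  }
  hit_date <- ms_to_date(hours_hit * MS_PER_HOUR)
  counts <- table(factor(as.character(hit_date),
                         levels = as.character(days)))
  data.frame(
    date = days,
    distinct_hours = as.integer(counts),
    valid = as.integer(counts) >= min_distinct_hours
  )
}

#' Apply the analysis-sample day and participant filter
#'
#' A valid day enters the analysis sample only if it belongs to some
#' 28-consecutive-day window containing at least `min_valid_in_window`
#' valid days; a participant is retained only if at least
#' `min_retained_days` days survive. Windows slide by calendar day over
#' the participant's observation span and are clipped at its edges (a
#' span shorter than 28 days forms a single window).
#'
#' @param day_valid Data frame with columns `date` and `valid` covering
#'   the observation span (missing dates are treated as invalid).
#' @param window_days Window length in days, default 28.
#' @param min_valid_in_window Minimum valid days a window must contain,
#'   default 14.
#' @param min_retained_days Minimum retained days for participant
#'   inclusion, default 28.
#' @return A list with `day_table` (`date`, `valid`, `retained`),
#'   `retained_days` (a `Date` vector), and `participant_retained`
#'   (logical).
#' @export
analysis_day_filter <- function(day_valid, window_days = 28,
                                min_valid_in_window = 14,
                                min_retained_days = 28) {
  stopifnot(all(c("date", "valid") %in% names(day_valid)))
  if (nrow(day_valid) == 0L) {
    return(list(day_table = data.frame(date = as.Date(character(0)),
                                       valid = logical(0),
                                       retained = logical(0)),
                retained_days = as.Date(character(0)),
                participant_retained = FALSE))
  }
  days <- seq(min(day_valid$date), max(day_valid$date), by = "day")
  v <- logical(length(days))
  v[match(day_valid$date[day_valid$valid], days)] <- TRUE
  n <- length(days)
  w <- min(window_days, n)
  # wsum[s] = number of valid days in the window starting at index s
  cs <- cumsum(c(0L, as.integer(v)))
  starts <- seq_len(n - w + 1L)
  wsum <- cs[starts + w] - cs[starts]
  good <- wsum >= min_valid_in_window
  retained <- logical(n)
  for (s in starts[good]) {
    idx <- s:(s + w - 1L)
    retained[idx] <- retained[idx] | v[idx]
  }
  day_table <- data.frame(date = days, valid = v, retained = retained)
  list(day_table = day_table,
       retained_days = days[retained],
       participant_retained = sum(retained) >= min_retained_days)
}
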