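#' Split bouts at UTC midnights
#'
#' Days run midnight-to-midnight in UTC (the logs' native clock), so a
#' bout crossing midnight is divided into per-day fragments. Total
#' duration is conserved exactly; fragment flags are inherited.
#'
#' @param bouts Sorted, non-overlapping bout data frame with finite ends.
#' @return A bout data frame in which every row lies within a single UTC
#'   date.
#' @export
split_at_midnight <- function(bouts) {
  .check_bouts(bouts)
  if (any(is.na(bouts$end_ms))) stop("bouts must have resolved ends")
  if (nrow(bouts) == 0L) return(bouts)
  pieces <- lapply(seq_len(nrow(bouts)), function(i) {
    s <- bouts$start_ms[i]
    e <- bouts$end_ms[i]
    cuts <- unique(c(s, seq(ceiling(s / MS_PER_DAY),
                            ceiling(e / MS_PER_DAY) - 1) * MS_PER_DAY, e))
    cuts <- cuts[cuts >= s & cuts <= e]
    k <- length(cuts) - 1L
    out <- bouts[rep(i, k), , drop = FALSE]
    out$start_ms <- cuts[-length(cuts)]
    out$end_ms <- cuts[-1L]
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Daily screen-time measures
#'
#' Computes, for each valid day, the four daily measures: total screen-on
#' time (minutes), number of screen-on bout fragments, mean on-bout
#' duration (total / count), mean off-bout duration (mean of the interior
#' gaps between consecutive fragments within the day; day-boundary
#' partial gaps are censored intervals and are excluded, so days with at
#' most one fragment have no off-bout measure), and the natural log of
#' the bout count (absent when the count is zero).
#'
#' Bouts must already be split at midnight ([split_at_midnight()]); a
#' fragment crossing midnight is a contract violation. Only valid days are
#' emitted.
#'
#' @param bouts Midnight-split bout data frame.
#' @param day_valid Data frame with columns `date` and `valid`.
#' @param participant_id Optional id copied into the output.
#' @return A data frame with one row per valid day: `date`,
#'   `total_on_minutes`, `on_bout_count`, `mean_on_bout_minutes`,
#'   `mean_off_bout_minutes`, `log_on_bout_count` (plus `participant_id`
#'   when given).
#' @export
daily_measures <- function(bouts, day_valid, participant_id = NULL) {
  .check_bouts(bouts)
  stopifnot(all(c("date", "valid") %in% names(day_valid)))
  if (nrow(bouts)) {
    same_day <- floor(bouts$start_ms / MS_PER_DAY) ==
      floor((bouts$end_ms - 1) / MS_PER_DAY)
    if (!all(same_day)) {
      stop("bouts must be split at midnight before daily_measures")
    }
  }
  valid_dates <- sort(day_valid$date[day_valid$valid])
  bd <- ms_to_date(bouts$start_ms)
  rows <- lapply(valid_dates, function(d) {
    b <- bouts[bd == d, , drop = FALSE]
    cnt <- nrow(b)
    total <- sum(b$end_ms - b$start_ms) / MS_PER_MIN
    mean_on <- if (cnt >= 1L) total / cnt else NA_real_
    mean_off <- if (cnt >= 2L) {
      mean(b$start_ms[-1L] - b$end_ms[-cnt]) / MS_PER_MIN
    } else {
      NA_real_
    }
    data.frame(date = d, total_on_minutes = total, on_bout_count = cnt,
               mean_on_bout_minutes = mean_on,
               mean_off_bout_minutes = mean_off,
               log_on_bout_count = if (cnt >= 1L) log(cnt) else NA_real_)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(date = as.Date(character(0)), total_on_minutes = numeric(0),
               on_bout_count = integer(0),
               mean_on_bout_minutes = numeric(0),
               mean_off_bout_minutes = numeric(0),
               log_on_bout_count = numeric(0))
  if (!is.null(participant_id)) {
    out <- cbind(participant_id = rep(participant_id, nrow(out)), out)
  }
  rownames(out) <- NULL
  out
}

#' Minute-level screen-on grid
#'
#' Distributes bout durations over the 1440 UTC minutes of each day:
#' `on_seconds` is the overlap (0--60 s) of the bouts with the half-open
#' minute `[t, t + 60 s)`, and `binary_on` is 1 exactly when any screen-on
#' time was recorded in that minute. Bouts need not be split at midnight.
#'
#' @param bouts Sorted, non-overlapping bout data frame with finite ends.
#' @param span Optional `Date` length-2 range of days the grid should
#'   cover; defaults to the dates spanned by the bouts. Days without bouts
#'   are all-zero rows.
#' @param participant_id Optional id copied into the output.
#' @return A data frame with `n_days * 1440` rows: `date`, `minute`
#'   (0--1439), `on_seconds`, `binary_on` (plus `participant_id` when
#'   given).
#' @export
minute_grid <- function(bouts, span = NULL, participant_id = NULL) {
  .check_bouts(bouts)
  if (any(is.na(bouts$end_ms))) stop("bouts must have resolved ends")
  if (is.null(span)) {
    if (nrow(bouts) == 0L) stop("no bouts and no span given")
    span <- c(ms_to_date(min(bouts$start_ms)),
              ms_to_date(max(bouts$end_ms - 1)))
  }
  span <- as.Date(span)
  day0 <- span[1]
  n_days <- as.integer(span[2] - span[1]) + 1L
  n_min <- n_days * 1440L
  origin_ms <- date_to_ms(day0)
  secs <- numeric(n_min)
  for (i in seq_len(nrow(bouts))) {
    s <- bouts$start_ms[i] - origin_ms
    e <- bouts$end_ms[i] - origin_ms
    if (e <= 0 || s >= n_min * MS_PER_MIN) next
    s <- max(s, 0); e <- min(e, n_min * MS_PER_MIN)
    m1 <- floor(s / MS_PER_MIN)
    m2 <- floor((e - 1) / MS_PER_MIN)
    if (m1 == m2) {
      secs[m1 + 1L] <- secs[m1 + 1L] + (e - s) / MS_PER_SEC
    } else {
      secs[m1 + 1L] <- secs[m1 + 1L] + ((m1 + 1) * MS_PER_MIN - s) / MS_PER_SEC
      secs[m2 + 1L] <- secs[m2 + 1L] + (e - m2 * MS_PER_MIN) / MS_PER_SEC
      if (m2 > m1 + 1) {
        mid <- (m1 + 2L):m2
        secs[mid] <- secs[mid] + 60
      }
    }
  }
  out <- data.frame(
    date = rep(day0 + seq_len(n_days) - 1L, each = 1440L),
    minute = rep.int(0:1439, n_days),
    on_seconds = secs,
    binary_on = as.integer(secs > 0)
  )
  if (!is.null(participant_id)) {
    out <- cbind(participant_id = rep(participant_id, nrow(out)), out)
  }
  out
}

#' Cohort summary of a daily measure over relative study time
#'
#' Aggregates one daily measure across participants for each day relative
#' to study start (median and 10th/25th/75th/90th percentiles), then
#' smooths each statistic with a centred 7-day moving average; edge days
#' use the available part of the window.
#'
#' @param measures Data frame with columns `participant_id`, `date`, and
#'   the measure named by `value`.
#' @param value Name of the measure column to summarise.
#' @param study_start Optional named vector/list mapping participant id to
#'   its study start `Date`; defaults to each participant's first date in
#'   `measures`.
#' @param smooth_days Moving-average window in days, default 7.
#' @return A data frame per relative day: `rel_day`, `n` (participants
#'   contributing), raw and smoothed `median`, `p10`, `p25`, `p75`, `p90`
#'   (smoothed columns prefixed `sm_`).
#' @export
cohort_daily_summary <- function(measures, value = "total_on_minutes",
                                 study_start = NULL, smooth_days = 7) {
  stopifnot(all(c("participant_id", "date", value) %in% names(measures)))
  if (nrow(measures) == 0L) stop("no measures supplied")
  if (is.null(study_start)) {
    study_start <- tapply(measures$date, measures$participant_id, min)
    study_start <- as.Date(study_start, origin = "1970-01-01")
  }
  rel <- as.integer(measures$date -
                      as.Date(study_start[as.character(
                        measures$participant_id)], origin = "1970-01-01"))
  x <- measures[[value]]
  keep <- !is.na(x)
  rel <- rel[keep]; x <- x[keep]
  rel_days <- seq(min(rel), max(rel))
  qs <- function(v) stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9),
                                    names = FALSE, type = 7)
  stat <- t(vapply(rel_days, function(d) {
    v <- x[rel == d]
    if (length(v)) c(length(v), qs(v)) else c(0, rep(NA_real_, 5))
  }, numeric(6)))
  out <- data.frame(rel_day = rel_days, n = as.integer(stat[, 1]),
                    p10 = stat[, 2], p25 = stat[, 3], median = stat[, 4],
                    p75 = stat[, 5], p90 = stat[, 6])
  sm <- function(v) {
    zoo::rollapply(v, width = smooth_days, FUN = mean, na.rm = TRUE,
                   partial = TRUE, align = "center")
  }
  for (col in c("p10", "p25", "median", "p75", "p90")) {
    out[[paste0("sm_", col)]] <- sm(out[[col]])
  }
  out
}
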