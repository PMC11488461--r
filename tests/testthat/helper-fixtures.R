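# Fixture builders shared across the suite. Everything is generated in
# code; no files ship with the tests except what the tests write to
# tempdirs themselves.

MS_MIN <- 60000
MS_HOUR <- 3600000
MS_DAY <- 86400000

# a day origin used by hand-built fixtures (2021-10-01 00:00 UTC)
T0 <- as.numeric(as.Date("2021-10-01")) * MS_DAY

mk_stream <- function(os, kind, ts, level = NULL) {
  level <- level %||% rep(NA_integer_, length(ts))
  event_stream("p1", os, data.frame(timestamp_ms = ts, kind = kind,
                                    battery_level = level))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

mk_bouts <- function(start_ms, end_ms) {
  data.frame(start_ms = start_ms, end_ms = end_ms,
             close_imputed = rep(FALSE, length(start_ms)),
             capped = rep(FALSE, length(start_ms)))
}

# iOS stream that is pure battery telemetry: events every `step_min`
# minutes across `n_days` days starting at T0
battery_stream <- function(step_min, n_days, level = 50L) {
  ts <- seq(T0, T0 + n_days * MS_DAY, by = step_min * MS_MIN)
  mk_stream("ios", rep("battery", length(ts)), ts,
            rep(level, length(ts)))
}

# random normalised open/close sequence (possibly ill-formed), sorted
random_event_seq <- function(n_max = 50) {
  n <- sample.int(n_max, 1)
  data.frame(
    timestamp_ms = sort(sample.int(1e6, n)),
    role = sample(c("open", "close"), n, replace = TRUE),
    battery_level = NA_integer_
  )
}

# independent oracle for pair_events(impute = FALSE): enumerate every
# adjacent index pair and keep the (open, close) ones with positive span
brute_force_pairs <- function(events) {
  scr <- events[events$role %in% c("open", "close"), , drop = FALSE]
  out <- mk_bouts(numeric(0), numeric(0))
  for (i in seq_len(nrow(scr) - 1L)) {
    if (scr$role[i] == "open" && scr$role[i + 1L] == "close" &&
        scr$timestamp_ms[i + 1L] > scr$timestamp_ms[i]) {
      out <- rbind(out, mk_bouts(scr$timestamp_ms[i],
                                 scr$timestamp_ms[i + 1L]))
    }
  }
  out
}

# random sorted non-overlapping bout set spanning a few days
random_bout_set <- function(n_max = 40, span_days = 3) {
  n <- sample.int(n_max, 1)
  edges <- sort(sample.int(span_days * MS_DAY - 1, 2 * n))
  mk_bouts(T0 + edges[seq(1, 2 * n, by = 2)],
           T0 + edges[seq(2, 2 * n, by = 2)])
}
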