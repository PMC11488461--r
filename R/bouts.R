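#' Extraction configuration for screen-on bout identification
#'
#' The default preprocessing imputes missing log events and caps individual
#' screen-on bouts at 30 minutes (roughly the 97th percentile of bout
#' durations in naturalistic logs). Three comparator modes probe the
#' sensitivity of downstream measures to these choices:
#' \describe{
#'   \item{`default`}{impute, cap at 30 minutes}
#'   \item{`comparator1`}{impute, cap at 360 minutes (6 hours)}
#'   \item{`comparator2`}{no imputation (only adjacent matching
#'     open/close pairs), no cap}
#'   \item{`comparator3`}{no imputation, cap at 30 minutes}
#' }
#' `mode = "custom"` leaves `impute` and `cap_minutes` to the caller.
#'
#' @param mode One of `"default"`, `"comparator1"`, `"comparator2"`,
#'   `"comparator3"`, `"custom"`.
#' @param impute,cap_minutes Only honoured with `mode = "custom"`;
#'   `cap_minutes = NULL` disables capping.
#' @param notification_min_seconds Android-only duration threshold below
#'   which a bout is attributed to a notification screen-wake and removed;
#'   `0` disables the filter. Default 10 seconds.
#' @return A list of class `extraction_config` with elements `mode`,
#'   `impute`, `cap_minutes`, `notification_min_seconds`.
#' @export
extraction_config <- function(mode = c("default", "comparator1",
                                       "comparator2", "comparator3",
                                       "custom"),
                              impute = TRUE, cap_minutes = 30,
                              notification_min_seconds = 10) {
  mode <- match.arg(mode)
  preset <- switch(mode,
    default = list(impute = TRUE, cap_minutes = 30),
    comparator1 = list(impute = TRUE, cap_minutes = 360),
    comparator2 = list(impute = FALSE, cap_minutes = NULL),
    comparator3 = list(impute = FALSE, cap_minutes = 30),
    custom = list(impute = impute, cap_minutes = cap_minutes)
  )
  if (!is.null(preset$cap_minutes) && preset$cap_minutes <= 0) {
    stop("cap_minutes must be positive (or NULL for no cap)")
  }
  if (notification_min_seconds < 0) {
    stop("notification_min_seconds must be non-negative")
  }
  structure(
    list(mode = mode, impute = preset$impute,
         cap_minutes = preset$cap_minutes,
         notification_min_seconds = notification_min_seconds),
    class = "extraction_config"
  )
}

# canonical empty bout frame
empty_bouts <- function() {
  data.frame(start_ms = numeric(0), end_ms = numeric(0),
             close_imputed = logical(0), capped = logical(0))
}

.check_bouts <- function(bouts) {
  stopifnot(is.data.frame(bouts),
            all(c("start_ms", "end_ms") %in% names(bouts)))
  fin <- !is.na(bouts$end_ms)
  if (is.unsorted(bouts$start_ms)) stop("bouts must be sorted by start_ms")
  if (any(bouts$end_ms[fin] <= bouts$start_ms[fin])) {
    stop("bouts must have end_ms > start_ms")
  }
  invisible(bouts)
}

#' Pair open/close events into screen-on bouts
#'
#' Runs a state machine over the normalised event roles. With
#' `impute = TRUE`, missing events are imputed: an `open` arriving while a
#' bout is already open closes the current bout at the new open's timestamp
#' (flagged `close_imputed`) and starts a new one; a `close` with no open
#' bout is dropped; a bout still open at end-of-stream is emitted with
#' `end_ms = NA` and `close_imputed = TRUE`, to be resolved by
#' [cap_bouts()] (closed at start + cap) or dropped when no cap is
#' configured. With `impute = FALSE`, only immediately adjacent
#' (`open`, `close`) pairs with no intervening screen event form bouts and
#' every unmatched event is discarded.
#'
#' Battery events are ignored. Zero-length bouts (close at the same
#' millisecond as open) are dropped.
#'
#' @param events Data frame from [normalize_events()], time-ordered.
#' @param impute Logical; see above.
#' @return A sorted, pairwise non-overlapping bout data frame with columns
#'   `start_ms`, `end_ms`, `close_imputed`, `capped` (all `FALSE` here).
#'   Attribute `n_dropped_close` counts discarded unmatched closes under
#'   imputation.
#' @export
pair_events <- function(events, impute = TRUE) {
  stopifnot(is.data.frame(events), all(c("timestamp_ms", "role") %in%
                                         names(events)))
  if (is.unsorted(events$timestamp_ms)) {
    stop("events must be time-ordered")
  }
  scr <- events[events$role %in% c("open", "close"), , drop = FALSE]
  n <- nrow(scr)
  if (n == 0L) {
    out <- empty_bouts()
    attr(out, "n_dropped_close") <- 0L
    return(out)
  }
  ts <- scr$timestamp_ms
  role <- scr$role
  if (!impute) {
    # adjacent (open, close) pairs; matches cannot overlap by construction
    i <- which(role[-n] == "open" & role[-1L] == "close")
    keep <- i[ts[i + 1L] > ts[i]]
    out <- data.frame(start_ms = ts[keep], end_ms = ts[keep + 1L],
                      close_imputed = rep(FALSE, length(keep)),
                      capped = rep(FALSE, length(keep)))
    if (nrow(out) == 0L) out <- empty_bouts()
    attr(out, "n_dropped_close") <- 0L
    return(out)
  }
  start <- numeric(n)
  end <- numeric(n)
  imput <- logical(n)
  k <- 0L
  open_t <- NA_real_
  dropped_close <- 0L
  emit <- function(s, e, im) {
    k <<- k + 1L
    start[k] <<- s; end[k] <<- e; imput[k] <<- im
  }
  for (j in seq_len(n)) {
    t <- ts[j]
    if (role[j] == "open") {
      if (!is.na(open_t)) {
        if (t > open_t) emit(open_t, t, TRUE)   # zero-length dropped
      }
      open_t <- t
    } else {                                    # close
      if (!is.na(open_t)) {
        if (t > open_t) emit(open_t, t, FALSE)
        open_t <- NA_real_
      } else {
        dropped_close <- dropped_close + 1L
      }
    }
  }
  if (!is.na(open_t)) emit(open_t, NA_real_, TRUE)  # trailing open
  out <- if (k > 0L) {
    data.frame(start_ms = start[seq_len(k)], end_ms = end[seq_len(k)],
               close_imputed = imput[seq_len(k)], capped = FALSE)
  } else {
    empty_bouts()
  }
  attr(out, "n_dropped_close") <- dropped_close
  out
}

#' Remove Android bouts attributed to notification screen-wakes
#'
#' Android screens light up briefly when notifications arrive, producing
#' short on/off pairs with no user interaction. For `os = "android"`,
#' bouts shorter than `min_seconds` are removed; for `os = "ios"` (where
#' unlock events already imply interaction) the input is returned
#' unchanged. Bouts with an unresolved (`NA`) end are retained.
#'
#' @param bouts Sorted bout data frame.
#' @param min_seconds Non-negative duration threshold in seconds; `0`
#'   disables the filter.
#' @param os `"ios"` or `"android"`.
#' @return The filtered bout frame, with attribute `n_filtered` counting
#'   removed bouts.
#' @export
filter_notification_bouts <- function(bouts, min_seconds = 10,
                                      os = c("ios", "android")) {
  os <- match.arg(os)
  .check_bouts(bouts)
  if (min_seconds < 0) stop("min_seconds must be non-negative")
  if (os == "ios" || min_seconds == 0 || nrow(bouts) == 0L) {
    attr(bouts, "n_filtered") <- 0L
    return(bouts)
  }
  dur_s <- (bouts$end_ms - bouts$start_ms) / MS_PER_SEC
  keep <- is.na(dur_s) | dur_s >= min_seconds
  out <- bouts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_filtered") <- sum(!keep)
  out
}

#' Cap individual screen-on bout durations
#'
#' Truncates every bout longer than `cap_minutes` to end at
#' `start + cap`, flagging it `capped`. Bouts left open at end-of-stream
#' by [pair_events()] (`end_ms = NA`) are closed at `start + cap`, or
#' dropped when `cap_minutes` is `NULL`.
#'
#' @param bouts Sorted bout data frame.
#' @param cap_minutes Positive cap in minutes, or `NULL` for no cap.
#' @return The capped bout frame; attribute `n_dropped_open` counts
#'   open-ended bouts dropped under `cap_minutes = NULL`.
#' @export
cap_bouts <- function(bouts, cap_minutes = 30) {
  .check_bouts(bouts)
  if (is.null(cap_minutes)) {
    keep <- !is.na(bouts$end_ms)
    out <- bouts[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_dropped_open") <- sum(!keep)
    return(out)
  }
  if (cap_minutes <= 0) stop("cap_minutes must be positive")
  cap_ms <- cap_minutes * MS_PER_MIN
  limit <- bouts$start_ms + cap_ms
  over <- is.na(bouts$end_ms) | bouts$end_ms > limit
  bouts$end_ms[over] <- limit[over]
  bouts$capped <- bouts$capped | over
  attr(bouts, "n_dropped_open") <- 0L
  bouts
}

#' Extract screen-on bouts from a raw event stream
#'
#' Full preprocessing composition: [normalize_events()] then
#' [pair_events()] (imputation per config), [filter_notification_bouts()]
#' (Android only, before capping so the cap has the last word on
#' duration), then [cap_bouts()]. Deterministic; output is sorted and
#' pairwise non-overlapping.
#'
#' @param stream An [event_stream()].
#' @param config An [extraction_config()].
#' @return A bout data frame (`start_ms`, `end_ms`, `close_imputed`,
#'   `capped`) with attributes `n_dropped_close`, `n_filtered`,
#'   `n_dropped_open` carried from the stages.
#' @examples
#' ev <- data.frame(timestamp_ms = c(0, 120000, 180000),
#'                  kind = c("screen_on", "screen_on", "screen_off"),
#'                  battery_level = NA_integer_)
#' s <- event_stream("p1", "android", ev)
#' extract_bouts(s, extraction_config("default",
#'                                    notification_min_seconds = 0))
#' @export
extract_bouts <- function(stream, config = extraction_config()) {
  stopifnot(inherits(stream, "event_stream"),
            inherits(config, "extraction_config"))
  ev <- normalize_events(stream)
  b <- pair_events(ev, impute = config$impute)
  n_dropped_close <- attr(b, "n_dropped_close")
  b <- filter_notification_bouts(b, config$notification_min_seconds,
                                 os = stream$os)
  n_filtered <- attr(b, "n_filtered")
  b <- cap_bouts(b, config$cap_minutes)
  attr(b, "n_dropped_close") <- n_dropped_close
  attr(b, "n_filtered") <- n_filtered
  b
}
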