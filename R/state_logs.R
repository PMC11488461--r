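#' Phone power-state event streams
#'
#' An `event_stream` is the in-memory form of one participant's raw
#' power-state log: a time-ordered sequence of screen events
#' (`unlocked`/`locked` on iOS, `screen_on`/`screen_off` on Android) and,
#' on iOS only, a `battery` event for every 1% change in battery charge
#' level. Timestamps are epoch milliseconds in UTC.
#'
#' @param participant_id Opaque participant identifier string.
#' @param os Operating system, `"ios"` or `"android"`. The OS determines
#'   which event kinds are admissible.
#' @param records A data frame with columns `timestamp_ms` (numeric epoch
#'   ms, non-negative), `kind` (one of `"unlocked"`, `"locked"`,
#'   `"screen_on"`, `"screen_off"`, `"battery"`), and `battery_level`
#'   (integer percent in 0--100, `NA` except on battery rows). Rows are
#'   stably sorted by timestamp, so ties keep their input order.
#'
#' @return An object of class `event_stream`: a list with elements
#'   `participant_id`, `os`, and `records` (sorted data frame as above).
#' @examples
#' ev <- data.frame(
#'   timestamp_ms = c(0, 61000, 90000),
#'   kind = c("unlocked", "locked", "battery"),
#'   battery_level = c(NA, NA, 87L)
#' )
#' s <- event_stream("p1", "ios", ev)
#' nrow(s$records)
#' @export
event_stream <- function(participant_id, os = c("ios", "android"), records) {
  os <- match.arg(os)
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    records <- data.frame(
      timestamp_ms = numeric(0), kind = character(0),
      battery_level = integer(0)
    )
  }
  required <- c("timestamp_ms", "kind", "battery_level")
  if (!all(required %in% names(records))) {
    stop("records must have columns timestamp_ms, kind, battery_level")
  }
  records <- records[required]
  records$timestamp_ms <- as.numeric(records$timestamp_ms)
  records$kind <- as.character(records$kind)
  records$battery_level <- as.integer(records$battery_level)
  if (any(records$timestamp_ms < 0, na.rm = TRUE) ||
      anyNA(records$timestamp_ms)) {
    stop("timestamp_ms must be non-negative and non-missing")
  }
  allowed <- if (os == "ios") c("unlocked", "locked", "battery") else
    c("screen_on", "screen_off")
  bad <- setdiff(unique(records$kind), allowed)
  if (length(bad)) {
    stop(sprintf("event kind(s) %s not admissible for os=%s",
                 paste(sQuote(bad), collapse = ", "), os))
  }
  is_batt <- records$kind == "battery"
  if (any(is_batt & is.na(records$battery_level)) ||
      any(!is_batt & !is.na(records$battery_level))) {
    stop("battery_level must be present exactly on battery rows")
  }
  if (any(records$battery_level < 0L, na.rm = TRUE) ||
      any(records$battery_level > 100L, na.rm = TRUE)) {
    stop("battery_level must lie in [0, 100]")
  }
  ord <- order(records$timestamp_ms)        # stable: ties keep file order
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  structure(
    list(participant_id = as.character(participant_id), os = os,
         records = records),
    class = "event_stream"
  )
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> participant %s (%s), %d events\n",
              x$participant_id, x$os, nrow(x$records)))
  if (nrow(x$records)) {
    span <- range(x$records$timestamp_ms)
    cat(sprintf("  span: %s .. %s UTC\n",
                format(as.POSIXct(span[1] / 1000, tz = "UTC")),
                format(as.POSIXct(span[2] / 1000, tz = "UTC"))))
    cat("  kinds:", paste(sprintf("%s=%d", names(table(x$records$kind)),
                                  table(x$records$kind)), collapse = " "),
        "\n")
  }
  invisible(x)
}

# canonical on-disk strings per OS; matching is case-insensitive + trimmed
.event_string_table <- function(os) {
  if (os == "ios") {
    c("unlocked" = "unlocked", "locked" = "locked", "battery" = "battery")
  } else {
    c("screen turned on" = "screen_on", "screen turned off" = "screen_off")
  }
}

.canonical_event_strings <- c(
  unlocked = "Unlocked", locked = "Locked", battery = "Battery",
  screen_on = "Screen turned on", screen_off = "Screen turned off"
)

#' Read a phone power-state log from CSV
#'
#' Parses one participant's raw log in the default dialect
#' (`timestamp,UTC time,event,level`), where `timestamp` is epoch
#' milliseconds (authoritative; the human-readable `UTC time` column is
#' ignored) and `level` is populated only on battery rows. Event-string
#' matching is case-insensitive and whitespace-trimmed; rows whose event
#' string is not recognised for the given OS are skipped and counted.
#'
#' @param path Path to a CSV file.
#' @param os `"ios"` or `"android"`.
#' @param participant_id Identifier for the returned stream; defaults to
#'   the file name without extension.
#' @param column_map Optional named character vector remapping the logical
#'   columns `timestamp`, `event`, `level` to the file's column names.
#'
#' @return An [event_stream()], sorted by timestamp, with attribute
#'   `n_skipped` giving the number of unrecognised rows.
#' @seealso [write_state_log()] for the inverse operation.
#' @export
read_state_log <- function(path, os = c("ios", "android"),
                           participant_id = NULL, column_map = NULL) {
  os <- match.arg(os)
  if (!file.exists(path)) stop("cannot read log file: ", path)
  participant_id <- participant_id %||%
    sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  cols <- c(timestamp = "timestamp", event = "event", level = "level")
  if (!is.null(column_map)) cols[names(column_map)] <- column_map
  missing_cols <- setdiff(cols[c("timestamp", "event")], names(raw))
  if (length(missing_cols)) {
    stop("log file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    out <- event_stream(participant_id, os,
                        data.frame(timestamp_ms = numeric(0),
                                   kind = character(0),
                                   battery_level = integer(0)))
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  tbl <- .event_string_table(os)
  key <- tolower(trimws(raw[[cols["timestamp"]]]))
  ts <- suppressWarnings(as.numeric(key))
  evt <- tolower(trimws(raw[[cols["event"]]]))
  kind <- unname(tbl[evt])
  keep <- !is.na(kind) & !is.na(ts)
  n_skipped <- sum(!keep)
  if (!any(keep)) {
    stop("no parseable event rows in ", path,
         " (", nrow(raw), " rows, all skipped)")
  }
  level <- rep(NA_integer_, nrow(raw))
  if (cols["level"] %in% names(raw)) {
    lv <- suppressWarnings(as.integer(trimws(raw[[cols["level"]]])))
    level[kind %in% "battery"] <- lv[kind %in% "battery"]
  }
  rec <- data.frame(timestamp_ms = ts[keep], kind = kind[keep],
                    battery_level = level[keep])
  out <- event_stream(participant_id, os, rec)
  if (n_skipped > 0L) {
    message(sprintf("read_state_log: skipped %d unrecognised row(s) in %s",
                    n_skipped, basename(path)))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a phone power-state log to CSV
#'
#' Serialises an [event_stream()] in the default dialect
#' (`timestamp,UTC time,event,level`). `read_state_log()` of the written
#' file reproduces the stream record-for-record.
#'
#' @param stream An [event_stream()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_state_log <- function(stream, path) {
  stopifnot(inherits(stream, "event_stream"))
  rec <- stream$records
  df <- data.frame(
    timestamp = format(rec$timestamp_ms, scientific = FALSE, trim = TRUE),
    `UTC time` = format(as.POSIXct(rec$timestamp_ms / 1000, tz = "UTC"),
                        "%Y-%m-%dT%H:%M:%OS3"),
    event = unname(.canonical_event_strings[rec$kind]),
    level = ifelse(is.na(rec$battery_level), "",
                   as.character(rec$battery_level)),
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Normalise OS-specific screen events into open/close roles
#'
#' Maps the two OS vocabularies onto a common one: `unlocked` and
#' `screen_on` become role `open`, `locked` and `screen_off` become role
#' `close`, and battery events pass through unchanged. Order is preserved.
#'
#' @param stream An [event_stream()].
#' @return A data frame with columns `timestamp_ms`, `role` (`"open"`,
#'   `"close"`, or `"battery"`), and `battery_level`.
#' @export
normalize_events <- function(stream) {
  stopifnot(inherits(stream, "event_stream"))
  map <- c(unlocked = "open", screen_on = "open",
           locked = "close", screen_off = "close",
           battery = "battery")
  rec <- stream$records
  data.frame(
    timestamp_ms = rec$timestamp_ms,
    role = unname(map[rec$kind]),
    battery_level = rec$battery_level
  )
}
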