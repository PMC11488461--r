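#' End-to-end pipeline over one participant's log file
#'
#' Runs read -> bout extraction -> validity labelling -> midnight split
#' -> daily measures + minute grid (and, when a transition instant is
#' given, the daylight-saving design restriction) and writes each stage's
#' output as CSV. Per-stage record counts are reported via `message()`.
#'
#' @param in_file Path to a power-state log CSV (see [read_state_log()]).
#' @param out_dir Output directory, created if needed.
#' @param os `"ios"` or `"android"`.
#' @param mode Extraction mode, see [extraction_config()].
#' @param cap_minutes,notification_min_seconds Passed to
#'   [extraction_config()] when `mode = "custom"` / always, respectively.
#' @param dst_transition_ms Optional epoch ms of a clock change; when
#'   given, a `dst_design.csv` restricted to `window_days` is written.
#' @param window_days Window half-width for the design, default 14.
#' @param participant_id Defaults to the input file name.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(in_file, out_dir, os = c("ios", "android"),
                         mode = "default", cap_minutes = 30,
                         notification_min_seconds = 10,
                         dst_transition_ms = NULL, window_days = 14,
                         participant_id = NULL) {
  os <- match.arg(os)
  if (!file.exists(in_file)) stop("input file not found: ", in_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- extraction_config(mode,
                           cap_minutes = cap_minutes,
                           notification_min_seconds =
                             notification_min_seconds)
  stream <- read_state_log(in_file, os = os,
                           participant_id = participant_id)
  pid <- stream$participant_id
  message(sprintf("read: %d events (%d skipped)",
                  nrow(stream$records), attr(stream, "n_skipped") %||% 0L))

  paths <- list()
  if (nrow(stream$records) == 0L) {
    warning("empty log file; writing empty outputs")
  }
  bouts <- extract_bouts(stream, cfg)
  message(sprintf("extract [%s]: %d bouts", cfg$mode, nrow(bouts)))

  day_valid <- if (os == "ios") {
    if (nrow(stream$records)) {
      vm <- ios_valid_minutes(stream)
      vd <- ios_valid_days(vm)
      data.frame(date = vd$date, valid = vd$valid,
                 valid_minutes = vd$valid_minutes)
    } else {
      data.frame(date = as.Date(character(0)), valid = logical(0),
                 valid_minutes = integer(0))
    }
  } else {
    if (nrow(bouts)) {
      vd <- android_valid_days(bouts)
      data.frame(date = vd$date, valid = vd$valid,
                 valid_minutes = NA_integer_)
    } else {
      data.frame(date = as.Date(character(0)), valid = logical(0),
                 valid_minutes = integer(0))
    }
  }
  filt <- analysis_day_filter(day_valid)
  vt <- merge(day_valid, filt$day_table[c("date", "retained")],
              by = "date", all.x = TRUE)
  vt <- cbind(participant_id = rep(pid, nrow(vt)), vt)
  paths$validity <- file.path(out_dir, "validity.csv")
  utils::write.csv(vt, paths$validity, row.names = FALSE)
  message(sprintf("validate: %d/%d valid days, retained participant: %s",
                  sum(day_valid$valid), nrow(day_valid),
                  filt$participant_retained))

  split <- split_at_midnight(bouts)
  bout_out <- data.frame(
    participant_id = rep(pid, nrow(split)), start_ms = split$start_ms,
    end_ms = split$end_ms,
    duration_s = (split$end_ms - split$start_ms) / MS_PER_SEC,
    close_imputed = split$close_imputed, capped = split$capped)
  paths$bouts <- file.path(out_dir, "bouts.csv")
  utils::write.csv(bout_out, paths$bouts, row.names = FALSE)

  dm <- daily_measures(split, day_valid, participant_id = pid)
  paths$daily <- file.path(out_dir, "daily_measures.csv")
  utils::write.csv(dm, paths$daily, row.names = FALSE)
  message(sprintf("daily: %d valid days of measures", nrow(dm)))

  if (nrow(bouts)) {
    grid <- minute_grid(bouts, participant_id = pid)
  } else {
    grid <- data.frame(participant_id = character(0),
                       date = as.Date(character(0)), minute = integer(0),
                       on_seconds = numeric(0), binary_on = integer(0))
  }
  paths$minutes <- file.path(out_dir, "minutes.csv")
  utils::write.csv(grid, paths$minutes, row.names = FALSE)

  if (!is.null(dst_transition_ms) && nrow(grid)) {
    des <- dst_design(grid, dst_transition_ms, window_days)
    paths$dst_design <- file.path(out_dir, "dst_design.csv")
    utils::write.csv(as.data.frame(des), paths$dst_design,
                     row.names = FALSE)
    message(sprintf("dst-design: %d participant-days",
                    nrow(des) / 1440))
  }
  invisible(paths)
}
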