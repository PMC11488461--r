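#' Build a daylight-saving-time minute-level design
#'
#' The biannual clock change is a sudden, exogenous shift in daily
#' routine, usable as a natural experiment on phone-use timing. This
#' restricts a minute grid to the participant-days within
#' `window_days` of the transition date and attaches the post-change
#' indicator (1 for days after the transition). The transition day itself
#' is excluded: its local clock is internally inconsistent.
#'
#' @param grid Minute grid from [minute_grid()]; must contain a
#'   `participant_id` column when pooling several participants.
#' @param transition_ms Epoch ms (UTC) of the clock-change instant; only
#'   its UTC date is used for windowing.
#' @param window_days Positive window half-width in days; 14 by default,
#'   with 7 and 28 the usual sensitivity choices.
#' @return A data frame of class `dst_design` with the grid columns plus
#'   `post` (0/1), and attributes `window_days` and `transition_ms`.
#' @export
dst_design <- function(grid, transition_ms, window_days = 14) {
  stopifnot(all(c("date", "minute", "binary_on") %in% names(grid)))
  if (window_days <= 0) stop("window_days must be positive")
  tdate <- ms_to_date(transition_ms)
  off <- as.integer(grid$date - tdate)
  keep <- off != 0L & abs(off) <= window_days
  out <- grid[keep, , drop = FALSE]
  out$post <- as.integer(out$date > tdate)
  rownames(out) <- NULL
  structure(out, window_days = window_days, transition_ms = transition_ms,
            class = c("dst_design", "data.frame"))
}

#' Naive pointwise log odds ratio of minute-level phone use
#'
#' For every minute of the day, estimates the log odds ratio of any
#' screen-on time in the post-change versus pre-change participant-days,
#' from the empirical group proportions with a 0.5/n continuity
#' correction applied when a proportion is exactly 0 or 1. This is a
#' deliberately simple pointwise empirical estimator — it ignores
#' within-participant correlation and provides no joint inference — meant
#' for sign- and magnitude-level checks on simulated designs, not as a
#' substitute for a functional mixed-model fit.
#'
#' @param design A [dst_design()] (or any data frame with `minute`,
#'   `binary_on`, `post`).
#' @return A data frame per minute: `minute`, `n_pre`, `n_post`, `p_pre`,
#'   `p_post`, `logodds`.
#' @export
pointwise_logodds <- function(design) {
  stopifnot(all(c("minute", "binary_on", "post") %in% names(design)))
  if (!any(design$post == 0L) || !any(design$post == 1L)) {
    stop("both pre and post groups must be non-empty")
  }
  agg <- function(g) {
    n <- tapply(g$binary_on, g$minute, length)
    p <- tapply(g$binary_on, g$minute, mean)
    data.frame(minute = as.integer(names(n)), n = as.integer(n),
               p = as.numeric(p))
  }
  pre <- agg(design[design$post == 0L, ])
  post <- agg(design[design$post == 1L, ])
  m <- merge(pre, post, by = "minute", suffixes = c("_pre", "_post"))
  adj <- function(p, n) pmin(pmax(p, 0.5 / n), 1 - 0.5 / n)
  p0 <- adj(m$p_pre, m$n_pre)
  p1 <- adj(m$p_post, m$n_post)
  data.frame(minute = m$minute, n_pre = m$n_pre, n_post = m$n_post,
             p_pre = m$p_pre, p_post = m$p_post,
             logodds = log((p1 / (1 - p1)) / (p0 / (1 - p0))))
}

#' Convert a log odds ratio to an odds ratio
#'
#' @param beta Finite log odds ratio (e.g. an average functional
#'   coefficient over a significant time window).
#' @return `exp(beta)`, the multiplicative change in odds.
#' @examples
#' logodds_to_or(0.71)   # odds roughly doubled
#' logodds_to_or(-1.13)  # odds roughly one third
#' @export
logodds_to_or <- function(beta) {
  stopifnot(is.numeric(beta), all(is.finite(beta)))
  exp(beta)
}
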