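# Shared time helpers. All timestamps are numeric epoch milliseconds (UTC);
# doubles hold integer ms exactly well past the year 200000, so no integer64
# machinery is needed.

MS_PER_SEC <- 1000
MS_PER_MIN <- 60000
MS_PER_HOUR <- 3600000
MS_PER_DAY <- 86400000

ms_to_date <- function(ms) {
  as.Date(floor(ms / MS_PER_DAY), origin = "1970-01-01")
}

date_to_ms <- function(d) {
  as.numeric(as.Date(d)) * MS_PER_DAY
}

# minute of the UTC day, 0..1439, under the half-open convention [t, t + 60 s)
ms_to_minute_of_day <- function(ms) {
  floor((ms %% MS_PER_DAY) / MS_PER_MIN)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
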