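#' Round half away from zero
#'
#' Percentages in reports are rounded *half-up* to a fixed number of decimals
#' (`round()` in R rounds half to even, which prints 0.5-boundary values
#' differently from the convention used in clinical reporting).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(46.05, 2.45), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small epsilon guards against values like 46.05 stored as 46.049999...
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a numerator over a denominator
#'
#' Returns `100 * num / den` rounded half-up to one decimal, or `NA` when the
#' denominator is zero (a percentage with an empty denominator is reported as
#' missing, never as 0 or Inf).
#'
#' @param num numerator count(s).
#' @param den denominator count(s).
#' @param digits decimals to keep (default 1, the usual reporting precision).
#' @return numeric vector of percentages, `NA` where `den == 0`.
#' @export
#' @examples
#' pct_of(70, 152)     # 46.1
#' pct_of(0, 0)        # NA
pct_of <- function(num, den, digits = 1) {
  out <- ifelse(den == 0, NA_real_, 100 * num / den)
  round_half_up(out, digits)
}

## ---- clock/time helpers (internal) ----------------------------------------

## All timestamps are naive wall-clock times represented as POSIXct in UTC:
## every calendar day has exactly 24 h and 1440/interval slots, and no DST
## arithmetic is ever applied.

# "HH:MM" or "HH:MM:SS(.fff)" -> seconds after midnight; NA if unparseable
parse_clock <- function(x) {
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})(?::([0-9]{2}(?:\\.[0-9]+)?))?$", x))
  ok <- lengths(m) == 4L
  if (any(ok)) {
    h <- as.numeric(vapply(m[ok], `[`, "", 2L))
    mi <- as.numeric(vapply(m[ok], `[`, "", 3L))
    s <- vapply(m[ok], `[`, "", 4L)
    s <- ifelse(s == "", 0, suppressWarnings(as.numeric(s)))
    val <- h * 3600 + mi * 60 + s
    val[h > 23 | mi > 59 | s >= 60] <- NA_real_
    out[ok] <- val
  }
  out
}

# seconds after midnight -> "HH:MM:SS.mmm" (milliseconds keep slot-boundary
# ties measure-zero on round trips through text sheets); rounding must never
# carry past the end of the day ("23:59:60" is not a clock time)
format_clock <- function(secs) {
  ms <- pmin(pmax(round(secs * 1000), 0), 86399999)
  h <- ms %/% 3600000
  mi <- (ms %% 3600000) %/% 60000
  s <- (ms %% 60000) / 1000
  sprintf("%02d:%02d:%06.3f", h, mi, s)
}

# Date + seconds-of-day -> POSIXct (naive, UTC)
ts_make <- function(date, secs = 0) {
  as.POSIXct(as.numeric(as.POSIXct(as.character(date), tz = "UTC")) + secs,
             tz = "UTC", origin = "1970-01-01")
}

ts_date <- function(ts) as.Date(ts, tz = "UTC")

# ISO day of week 1 (Mon) .. 7 (Sun)
day_of_week <- function(x) as.integer(format(as.POSIXct(x, tz = "UTC"), "%u"))

is_weekend <- function(x) day_of_week(x) >= 6L

daytype_of <- function(x) ifelse(is_weekend(x), "weekend", "weekday")

# "HH:MM" slot label for a timestamp
slot_label_of <- function(ts) format(ts, "%H:%M", tz = "UTC")

## quantiles: linear-interpolation convention (stats::quantile type 7),
## recorded in output metadata wherever summaries are emitted
q1_of <- function(x) unname(quantile(x, 0.25, type = 7, names = FALSE))
q3_of <- function(x) unname(quantile(x, 0.75, type = 7, names = FALSE))

`%||%` <- function(a, b) if (is.null(a)) b else a
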