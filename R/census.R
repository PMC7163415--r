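## Expansion of stay intervals and shift segments onto the
## unit x day x slot lattice. Counting is point-in-time sampling at the slot
## instant with half-open membership (entry <= t < exit), so an
## instantaneous transfer never double-counts a patient in two units.

#' Build the unit x day x slot lattice
#'
#' @param units character vector of unit identifiers.
#' @param start_date,end_date first and last calendar day (inclusive).
#' @param interval_minutes slot length; must divide 1440. The default 30
#'   yields 48 data points per day.
#' @return object of class `slot_grid`: list with `units`, `days`,
#'   `interval_minutes`, `slots_per_day` and `slot_times` (the POSIXct slot
#'   instants of one unit, length `days * slots_per_day`).
#' @export
#' @examples
#' g <- build_slot_grid("U01", "2015-01-01", "2015-01-01")
#' g$slots_per_day   # 48
build_slot_grid <- function(units, start_date, end_date,
                            interval_minutes = 30) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date < start_date) stop("end_date must be >= start_date")
  if (interval_minutes <= 0 || 1440 %% interval_minutes != 0)
    stop("interval_minutes must be a positive divisor of 1440")
  units <- unique(as.character(units))
  if (length(units) == 0) stop("at least one unit is required")
  days <- seq(start_date, end_date, by = "day")
  spd <- as.integer(1440 / interval_minutes)
  slot_times <- ts_make(start_date) +
    seq(0, length(days) * 86400 - 1, by = interval_minutes * 60)
  structure(list(units = units, days = days,
                 interval_minutes = as.integer(interval_minutes),
                 slots_per_day = spd, slot_times = slot_times),
            class = "slot_grid")
}

#' @export
print.slot_grid <- function(x, ...) {
  cat("<slot_grid> ", length(x$units), " units x ", length(x$days),
      " days x ", x$slots_per_day, " slots = ",
      length(x$units) * length(x$days) * x$slots_per_day, " points\n",
      sep = "")
  invisible(x)
}

# occupancy of half-open intervals sampled at the slot instants:
# count at slot j = #{i : start_i <= slot_j < end_i}
interval_slot_counts <- function(start_ts, end_ts, slot_times) {
  k <- length(slot_times)
  if (length(start_ts) == 0) return(integer(k))
  s <- as.numeric(start_ts); e <- as.numeric(end_ts)
  v <- as.numeric(slot_times)
  i_start <- findInterval(s, v, left.open = TRUE) + 1L # first slot >= start
  i_end <- findInterval(e, v, left.open = TRUE) + 1L   # first slot >= end
  i_start <- pmax(i_start, 1L)
  i_end <- pmin(i_end, k + 1L)
  keep <- i_start < i_end & i_start <= k
  delta <- tabulate(i_start[keep], nbins = k) - tabulate(i_end[keep], nbins = k)
  cumsum(delta)
}

check_units_in_grid <- function(x, grid, what) {
  extra <- setdiff(unique(x), grid$units)
  if (length(extra))
    stop(what, " reference unit(s) absent from the grid: ",
         paste(extra, collapse = ", "))
}

#' Patient census at every slot instant
#'
#' A patient is counted on a unit at slot time `t` iff the stay satisfies
#' `entry_ts <= t < exit_ts`. Stays overlapping the grid edges contribute
#' to the slots they cover (censoring at the study window).
#'
#' @param stays tibble with `unit_id`, `entry_ts`, `exit_ts`.
#' @param grid a [build_slot_grid()].
#' @return tibble (`unit_id`, `ts`, `n_patients`) covering the full lattice.
#' @export
count_patients <- function(stays, grid) {
  stopifnot(inherits(grid, "slot_grid"))
  check_units_in_grid(stays$unit_id, grid, "stay")
  out <- lapply(grid$units, function(u) {
    su <- stays[stays$unit_id == u, ]
    tibble::tibble(unit_id = u, ts = grid$slot_times,
                   n_patients = interval_slot_counts(su$entry_ts, su$exit_ts,
                                                     grid$slot_times))
  })
  dplyr::bind_rows(out)
}

#' Nurse census per qualification group at every slot instant
#'
#' A nurse is counted at slot time `t` iff one of her working segments
#' satisfies `start_ts <= t < end_ts`; a nurse on break at `t` is therefore
#' not counted. Only groups 1-3 carry segments.
#'
#' @param segments tibble with `unit_id`, `group` (1-3), `start_ts`,
#'   `end_ts`.
#' @param grid a [build_slot_grid()].
#' @return tibble (`unit_id`, `ts`, `n_rn`, `n_lpn`, `n_other`).
#' @export
count_nurses <- function(segments, grid) {
  stopifnot(inherits(grid, "slot_grid"))
  check_units_in_grid(segments$unit_id, grid, "segment")
  out <- lapply(grid$units, function(u) {
    su <- segments[segments$unit_id == u, ]
    cols <- lapply(1:3, function(g) {
      sg <- su[su$group == g, ]
      interval_slot_counts(sg$start_ts, sg$end_ts, grid$slot_times)
    })
    tibble::tibble(unit_id = u, ts = grid$slot_times,
                   n_rn = cols[[1]], n_lpn = cols[[2]], n_other = cols[[3]])
  })
  dplyr::bind_rows(out)
}

#' Combined patient and nurse census
#'
#' @param stays,segments see [count_patients()] and [count_nurses()].
#' @param grid a [build_slot_grid()].
#' @return tibble (`unit_id`, `ts`, `n_patients`, `n_rn`, `n_lpn`,
#'   `n_other`).
#' @export
build_census <- function(stays, segments, grid) {
  dplyr::inner_join(count_patients(stays, grid), count_nurses(segments, grid),
                    by = c("unit_id", "ts"))
}

#' Summaries of daily-only staff groups (students, externals)
#'
#' Groups 4-5 have no working-time breakdown; only daily presence counts
#' exist. This summarizes them per unit and group over a full day range:
#' days without a presence row count as zero.
#'
#' @param daily_presence tibble (`date`, `unit_id`, `group`, `count`), as
#'   produced by [link_nurse_side()].
#' @param days vector of all days of the study period (zero-filled).
#' @return tibble per unit x group with `total`, `daily_mean`,
#'   `daily_median`, `daily_max`.
#' @export
daily_presence_summary <- function(daily_presence, days) {
  days <- as.Date(days)
  combos <- tidyr::expand_grid(
    unit_id = unique(daily_presence$unit_id),
    group = unique(daily_presence$group),
    date = days)
  if (nrow(combos) == 0)
    return(tibble::tibble(unit_id = character(), group = integer(),
                          total = numeric(), daily_mean = numeric(),
                          daily_median = numeric(), daily_max = numeric()))
  combos |>
    dplyr::left_join(daily_presence,
                     by = c("unit_id", "group", "date")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::group_by(.data$unit_id, .data$group) |>
    dplyr::summarise(total = sum(.data$count),
                     daily_mean = mean(.data$count),
                     daily_median = median(.data$count),
                     daily_max = max(.data$count), .groups = "drop")
}
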