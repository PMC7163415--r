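## Admission / discharge / transfer counts per slot and their
## census-normalized turnover ratios. An event with timestamp tau belongs to
## the slot whose half-open window [t, t + interval) contains tau; a
## transfer contributes one transfer-out on the source unit and one
## transfer-in on the destination unit at the same instant.

#' Count ADT events per unit and slot
#'
#' @param stays tibble with `unit_id`, `entry_ts`, `exit_ts`, `entry_kind`
#'   (admission/transfer_in), `exit_kind` (discharge/transfer_out).
#' @param grid a [build_slot_grid()].
#' @return tibble over the full lattice (`unit_id`, `ts`, `n_admissions`,
#'   `n_discharges`, `n_transfers_in`, `n_transfers_out`), with attribute
#'   `n_excluded` giving the number of events outside the grid span.
#' @export
count_events <- function(stays, grid) {
  stopifnot(inherits(grid, "slot_grid"))
  check_units_in_grid(stays$unit_id, grid, "stay")
  events <- dplyr::bind_rows(
    tibble::tibble(unit_id = stays$unit_id, ts = stays$entry_ts,
                   kind = stays$entry_kind),
    tibble::tibble(unit_id = stays$unit_id, ts = stays$exit_ts,
                   kind = stays$exit_kind))
  v <- as.numeric(grid$slot_times)
  step <- grid$interval_minutes * 60
  slot_i <- findInterval(as.numeric(events$ts), v)
  in_span <- slot_i >= 1L & as.numeric(events$ts) < v[length(v)] + step
  n_excluded <- sum(!in_span)
  events <- events[in_span, ]
  events$ts <- grid$slot_times[slot_i[in_span]]

  counts <- events |>
    dplyr::count(.data$unit_id, .data$ts, .data$kind) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "n",
                       values_fill = 0L)
  for (k in c("admission", "discharge", "transfer_in", "transfer_out"))
    if (is.null(counts[[k]])) counts[[k]] <- 0L

  lattice <- tidyr::expand_grid(unit_id = grid$units, ts = grid$slot_times)
  out <- lattice |>
    dplyr::left_join(counts, by = c("unit_id", "ts")) |>
    dplyr::transmute(
      .data$unit_id, .data$ts,
      n_admissions = dplyr::coalesce(.data$admission, 0L),
      n_discharges = dplyr::coalesce(.data$discharge, 0L),
      n_transfers_in = dplyr::coalesce(.data$transfer_in, 0L),
      n_transfers_out = dplyr::coalesce(.data$transfer_out, 0L))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Normalize event counts by the patient census
#'
#' Divides each of the four per-slot event counts by the number of patients
#' present at that data point (the census sampled at the slot instant).
#' Slots with zero census get missing ratios - the counts are preserved,
#' never inflated to infinity or capped. Ratios can exceed 1.
#'
#' @param events tibble from [count_events()].
#' @param census tibble from [count_patients()] or [build_census()] on the
#'   same grid.
#' @return the events tibble extended by `n_patients` and `r_admissions`,
#'   `r_discharges`, `r_transfers_in`, `r_transfers_out`.
#' @export
normalize_turnover <- function(events, census) {
  if (nrow(events) != nrow(census))
    stop("events and census are not on the same grid")
  out <- dplyr::inner_join(events,
                           census[, c("unit_id", "ts", "n_patients")],
                           by = c("unit_id", "ts"))
  if (nrow(out) != nrow(events))
    stop("events and census are not on the same grid")
  div <- function(n, d) ifelse(d == 0, NA_real_, n / d)
  dplyr::mutate(out,
    r_admissions = div(.data$n_admissions, .data$n_patients),
    r_discharges = div(.data$n_discharges, .data$n_patients),
    r_transfers_in = div(.data$n_transfers_in, .data$n_patients),
    r_transfers_out = div(.data$n_transfers_out, .data$n_patients))
}

#' Department turnover profiles by daytype and slot of day
#'
#' Means of the unit-level turnover ratios per department, weekday/weekend
#' and slot of the day (missing unit values excluded). Exit ratios
#' (discharges, transfers out) are emitted with a negative sign - the
#' "leaving" side of a diverging bar chart - while the retained mean counts
#' stay unsigned.
#'
#' @param points tibble from [normalize_turnover()].
#' @param unit_map tibble (`unit_id`, `department`).
#' @return tibble (`department`, `daytype`, `slot`, signed mean ratios
#'   `r_admissions`, `r_transfers_in`, `r_discharges`, `r_transfers_out`,
#'   unsigned mean counts `n_admissions`, ..., and `n_units`).
#' @export
aggregate_profiles <- function(points, unit_map) {
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  points |>
    dplyr::inner_join(unit_map, by = "unit_id") |>
    dplyr::mutate(daytype = daytype_of(.data$ts),
                  slot = slot_label_of(.data$ts)) |>
    dplyr::group_by(.data$unit_id, .data$department, .data$daytype,
                    .data$slot) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("r_"), mean_or_na),
                     dplyr::across(dplyr::starts_with("n_"), mean),
                     .groups = "drop") |>
    dplyr::group_by(.data$department, .data$daytype, .data$slot) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("r_"), mean_or_na),
                     dplyr::across(dplyr::starts_with("n_"), mean),
                     n_units = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(r_discharges = -.data$r_discharges,
                  r_transfers_out = -.data$r_transfers_out)
}
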