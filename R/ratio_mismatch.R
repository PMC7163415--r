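## Patient-to-nurse ratio series per nurse group, the median-based extreme
## mismatch thresholds (ELT = median/2, EHT = 1.5 * median), key-timepoint
## summaries and per-department mean profiles.

#' Patient-to-nurse ratio at every census point
#'
#' One ratio per census point and nurse group 1-3:
#' `n_patients / n_nurses`. Points where no nurse of the group is present
#' get a missing ratio (never 0 or infinity); they are excluded from medians
#' and percentage denominators downstream but remain countable through the
#' `n_nurses` column.
#'
#' @param census tibble from [build_census()].
#' @return long tibble (`unit_id`, `ts`, `group` in rn/lpn/other,
#'   `n_patients`, `n_nurses`, `ratio`).
#' @export
compute_ratios <- function(census) {
  stopifnot(all(c("unit_id", "ts", "n_patients", "n_rn", "n_lpn", "n_other")
                %in% names(census)))
  census |>
    tidyr::pivot_longer(cols = c("n_rn", "n_lpn", "n_other"),
                        names_to = "group", names_prefix = "n_",
                        values_to = "n_nurses") |>
    dplyr::mutate(ratio = ifelse(.data$n_nurses == 0, NA_real_,
                                 .data$n_patients / .data$n_nurses)) |>
    dplyr::select("unit_id", "ts", "group", "n_patients", "n_nurses", "ratio")
}

#' Extreme-mismatch thresholds and classification
#'
#' For each stratum (unit x nurse group by default), computes the median and
#' IQR of the non-missing ratio series over the whole period, the extreme
#' lower threshold `elt = median - median/2 = median/2`, the extreme higher
#' threshold `eht = median + median/2 = 1.5 * median`, and the percentages of
#' points strictly below the ELT, strictly above the EHT, and within the
#' normal band (inclusive). Strata with median 0 are flagged `degenerate`
#' (their ELT and EHT collapse to 0 and every nonzero ratio is "extreme");
#' all-missing strata are flagged `unavailable`. Quantiles use the
#' linear-interpolation convention (`stats::quantile` type 7).
#'
#' @param ratios tibble from [compute_ratios()].
#' @param by character vector of stratification columns.
#' @return one row per stratum with `median`, `q1`, `q3`, `elt`, `eht`,
#'   `pct_below_elt`, `pct_above_eht`, `pct_normal`, `n_points`,
#'   `n_zero_nurse`, `degenerate`, `unavailable`.
#' @export
#' @examples
#' r <- tibble::tibble(unit_id = "U", ts = Sys.time(), group = "rn",
#'                     n_patients = 1:100, n_nurses = 1, ratio = 1:100)
#' compute_thresholds(r)[, c("median", "elt", "eht", "pct_below_elt")]
compute_thresholds <- function(ratios, by = c("unit_id", "group")) {
  ratios |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_points = sum(!is.na(.data$ratio)),
      n_zero_nurse = sum(.data$n_nurses == 0),
      median = if (.data$n_points[1] > 0) median(.data$ratio, na.rm = TRUE)
               else NA_real_,
      q1 = if (.data$n_points[1] > 0) q1_of(.data$ratio[!is.na(.data$ratio)])
           else NA_real_,
      q3 = if (.data$n_points[1] > 0) q3_of(.data$ratio[!is.na(.data$ratio)])
           else NA_real_,
      elt = .data$median / 2,
      eht = 1.5 * .data$median,
      pct_below_elt = 100 * mean(.data$ratio[!is.na(.data$ratio)] < .data$elt),
      pct_above_eht = 100 * mean(.data$ratio[!is.na(.data$ratio)] > .data$eht),
      pct_normal = 100 - .data$pct_below_elt - .data$pct_above_eht,
      degenerate = !is.na(.data$median) & .data$median == 0,
      unavailable = .data$n_points[1] == 0,
      .groups = "drop")
}

#' Key-timepoint ratio summaries by department and daytype
#'
#' Median (IQR) of the ratio series at fixed clock times of the day
#' (02:00, 10:00, 18:00 by default), split into weekdays and weekends
#' (Saturday/Sunday) and stratified by department and nurse group. The
#' summary pools all unit-level points of a department.
#'
#' @param ratios tibble from [compute_ratios()].
#' @param unit_map tibble (`unit_id`, `department`).
#' @param timepoints character clock labels of the slots to summarise.
#' @return tibble (`department`, `group`, `timepoint`, `daytype`, `median`,
#'   `q1`, `q3`, `n`).
#' @export
key_timepoint_summary <- function(ratios, unit_map,
                                  timepoints = c("02:00", "10:00", "18:00")) {
  ratios |>
    dplyr::mutate(timepoint = slot_label_of(.data$ts),
                  daytype = daytype_of(.data$ts)) |>
    dplyr::filter(.data$timepoint %in% timepoints, !is.na(.data$ratio)) |>
    dplyr::inner_join(unit_map, by = "unit_id") |>
    dplyr::group_by(.data$department, .data$group, .data$timepoint,
                    .data$daytype) |>
    dplyr::summarise(median = median(.data$ratio), q1 = q1_of(.data$ratio),
                     q3 = q3_of(.data$ratio), n = dplyr::n(),
                     .groups = "drop")
}

#' Department mean profiles across units with confidence intervals
#'
#' For every department, weekday-of-week and slot-of-day: each unit's mean
#' value is computed first (over all days of the period), then the
#' across-unit mean with a t-based confidence interval on the unit means.
#' Departments with a single unit get a mean and a missing CI.
#'
#' @param series long tibble with `unit_id`, `ts` and a value column.
#' @param unit_map tibble (`unit_id`, `department`).
#' @param value name of the value column (default `"ratio"`); if the series
#'   has a `group` column the profiles are additionally stratified by it.
#' @param level confidence level (default 0.95).
#' @return tibble (`department`[, `group`], `dow`, `slot`, `mean`, `ci_lo`,
#'   `ci_hi`, `n_units`).
#' @export
department_mean_ci <- function(series, unit_map, value = "ratio",
                               level = 0.95) {
  grp <- intersect("group", names(series))
  unit_means <- series |>
    dplyr::mutate(dow = day_of_week(.data$ts),
                  slot = slot_label_of(.data$ts)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("unit_id", grp, "dow", "slot")))) |>
    dplyr::summarise(unit_mean = mean(.data[[value]], na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::inner_join(unit_map, by = "unit_id")
  alpha <- 1 - level
  unit_means |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("department", grp, "dow", "slot")))) |>
    dplyr::summarise(
      n_units = sum(!is.na(.data$unit_mean)),
      mean = mean(.data$unit_mean, na.rm = TRUE),
      se = ifelse(.data$n_units > 1,
                  sd(.data$unit_mean, na.rm = TRUE) / sqrt(.data$n_units),
                  NA_real_),
      ci_lo = .data$mean - qt(1 - alpha / 2, pmax(.data$n_units - 1, 1)) * .data$se,
      ci_hi = .data$mean + qt(1 - alpha / 2, pmax(.data$n_units - 1, 1)) * .data$se,
      .groups = "drop") |>
    dplyr::select(-"se")
}
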