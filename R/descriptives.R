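## Department-level descriptive overview: volumes, age, length of stay,
## patients/day/unit and the two most common ICD-10 chapter diagnoses.

#' Length of stay in whole days
#'
#' Calendar-date difference `discharge_date - admission_date`; clock times
#' are ignored, so a same-day episode has LOS 0.
#'
#' @param admission_date,discharge_date `Date` vectors (or coercible).
#' @return integer vector of days.
#' @export
#' @examples
#' compute_los("2015-01-01", "2015-01-08")   # 7
#' compute_los("2016-02-28", "2016-03-01")   # 2 (leap year)
compute_los <- function(admission_date, discharge_date) {
  a <- as.Date(admission_date); d <- as.Date(discharge_date)
  bad <- !is.na(a) & !is.na(d) & d < a
  if (any(bad)) stop("discharge before admission for ", sum(bad), " case(s)")
  as.integer(d - a)
}

#' Department descriptive overview
#'
#' One row per department: number of patients and units, age mean (SD) and
#' median (IQR), LOS median (IQR), patients/day/unit median (IQR), and the
#' two most common chapter-level diagnoses with incidence n/N (%).
#'
#' The daily patient count of a unit is the census sampled at a fixed daily
#' reference slot (12:00 by default, configurable); ties in the top-2
#' chapter ranking are broken by chapter label order.
#'
#' @param linked a `wardflow_linked` dataset (needs `cases` and `units`).
#' @param census tibble from [count_patients()] or [build_census()].
#' @param reference_slot clock label of the daily reference census slot.
#' @return tibble, one row per department, ordered by `n_patients`
#'   decreasing.
#' @export
department_overview <- function(linked, census, reference_slot = "12:00") {
  cases <- linked$cases
  units <- linked$units

  daily <- census |>
    dplyr::filter(slot_label_of(.data$ts) == reference_slot) |>
    dplyr::inner_join(units, by = "unit_id") |>
    dplyr::group_by(.data$department) |>
    dplyr::summarise(pdu_median = median(.data$n_patients),
                     pdu_q1 = q1_of(.data$n_patients),
                     pdu_q3 = q3_of(.data$n_patients), .groups = "drop")

  top2 <- cases |>
    dplyr::count(.data$department, .data$chapter, name = "n_dx") |>
    dplyr::group_by(.data$department) |>
    dplyr::arrange(dplyr::desc(.data$n_dx), .data$chapter,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = 2) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(names_from = "rank",
                       values_from = c("chapter", "n_dx"),
                       names_sep = "")
  for (col in c("chapter1", "chapter2"))
    if (is.null(top2[[col]])) top2[[col]] <- NA_character_
  for (col in c("n_dx1", "n_dx2"))
    if (is.null(top2[[col]])) top2[[col]] <- NA_integer_

  n_units <- units |>
    dplyr::count(.data$department, name = "n_units")

  overview <- cases |>
    dplyr::group_by(.data$department) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      age_mean = mean(.data$age_years), age_sd = sd(.data$age_years),
      age_median = median(.data$age_years),
      age_q1 = q1_of(.data$age_years), age_q3 = q3_of(.data$age_years),
      los_median = median(.data$los_days),
      los_q1 = q1_of(.data$los_days), los_q3 = q3_of(.data$los_days),
      .groups = "drop") |>
    dplyr::left_join(n_units, by = "department") |>
    dplyr::left_join(daily, by = "department") |>
    dplyr::left_join(top2, by = "department") |>
    dplyr::mutate(
      dx1_pct = pct_of(.data$n_dx1, .data$n_patients),
      dx2_pct = pct_of(.data$n_dx2, .data$n_patients)) |>
    dplyr::arrange(dplyr::desc(.data$n_patients))
  overview
}
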