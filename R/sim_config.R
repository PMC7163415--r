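#' Default three-shift roster template
#'
#' One entry per shift with clock boundaries, staffing levels for nurse groups
#' 1-3 (RN/LPN/other) on weekdays and weekends, and a break rule: a clock
#' window within which each nurse takes one unpaid break of the given length
#' (breaks split a shift into two working segments). Shifts whose end time is
#' not after their start time run across midnight into the next day.
#'
#' @return list of shift definitions usable as `shift_template` in
#'   [sim_config()].
#' @export
default_shift_template <- function() {
  list(
    list(label = "night", start = "23:00", end = "07:15",
         weekday = c(rn = 1, lpn = 0, other = 0),
         weekend = c(rn = 1, lpn = 0, other = 0),
         break_window = c("03:00", "05:00"), break_minutes = 30),
    list(label = "morning", start = "07:00", end = "15:30",
         weekday = c(rn = 3, lpn = 1, other = 1),
         weekend = c(rn = 2, lpn = 0, other = 1),
         break_window = c("11:30", "13:30"), break_minutes = 30),
    list(label = "evening", start = "15:00", end = "23:15",
         weekday = c(rn = 2, lpn = 1, other = 0),
         weekend = c(rn = 2, lpn = 0, other = 0),
         break_window = c("18:30", "20:00"), break_minutes = 30)
  )
}

#' Default hour-by-weekday admission intensity profile
#'
#' A 24 x 7 matrix of admissions per hour per unit (rows = hour of day 0-23,
#' columns = ISO weekday 1-7). The default shape has a pronounced
#' morning peak (08:00-10:00), moderate daytime activity, a quiet night, and
#' reduced weekend intake - the diurnal demand pattern typical of acute-care
#' wards.
#'
#' @param base overnight baseline rate (admissions/hour/unit).
#' @param day daytime (10:00-18:00) rate.
#' @param peak morning-peak (08:00-10:00) rate.
#' @param weekend_factor multiplier applied to Saturday and Sunday columns.
#' @return a 24 x 7 numeric matrix.
#' @export
default_admission_profile <- function(base = 0.05, day = 0.25, peak = 0.6,
                                      weekend_factor = 0.6) {
  hourly <- rep(base, 24)
  hourly[9:10] <- peak          # hours 8 and 9 (08:00-10:00)
  hourly[11:19] <- day          # 10:00-19:00
  hourly[20:23] <- base * 2     # evening tail
  m <- matrix(rep(hourly, 7), nrow = 24, ncol = 7)
  m[, 6:7] <- m[, 6:7] * weekend_factor
  dimnames(m) <- list(hour = 0:23, dow = 1:7)
  m
}

default_chapter_weights <- function(department) {
  # crude department-typical ICD-10 chapter case mixes for the generator
  switch(department,
    "Cardiology & Cardiovascular Surgery" = c(
      "Circulatory system diseases" = 0.85, "Injury and poisoning" = 0.05,
      "Respiratory system diseases" = 0.05, "Endocrine, nutritional and metabolic diseases" = 0.05),
    "Maternity & Gynecology" = c(
      "Pregnancy, childbirth and the puerperium" = 0.6, "Tumors" = 0.17,
      "Genitourinary system diseases" = 0.15, "Certain conditions originating in the perinatal period" = 0.08),
    "Internal Medicine" = c(
      "Circulatory system diseases" = 0.2, "Infectious and parasitic diseases" = 0.1,
      "Respiratory system diseases" = 0.2, "Digestive system diseases" = 0.2,
      "Endocrine, nutritional and metabolic diseases" = 0.15, "Tumors" = 0.15),
    # fallback: a broad mix
    c("Circulatory system diseases" = 0.25, "Tumors" = 0.2,
      "Injury and poisoning" = 0.2, "Digestive system diseases" = 0.15,
      "Respiratory system diseases" = 0.2)
  )
}

#' Build a ward-simulation configuration
#'
#' Assembles and validates the full parameter set of the synthetic hospital
#' generator: the unit/department layout, the admission intensity, the
#' length-of-stay and age distributions, the roster template, the nurse group
#' mix, and the data-quality defect rates that the linkage stage must cope
#' with (nurses without working-time records, outpatient cases, healthy
#' newborns in the maternity department).
#'
#' @param departments named list/vector mapping department label to its number
#'   of units.
#' @param start_date,end_date calendar bounds of the simulation horizon
#'   (inclusive), coercible with `as.Date()`.
#' @param admission_rate either a single nonnegative number (constant
#'   admissions/hour/unit) or a 24 x 7 matrix as produced by
#'   [default_admission_profile()].
#' @param unit_rate_multiplier optional named vector of per-unit multipliers
#'   on the admission rate (default 1 for every unit).
#' @param los_dist length-of-stay distribution, either one spec for all
#'   departments or a named list per department. A spec is a list with
#'   `family` in `"lognormal"`, `"gamma"`, `"exponential"` and the matching
#'   parameters (`meanlog`/`sdlog`, `shape`/`rate`, or `mean_days`); values
#'   are in days.
#' @param transfer_prob expected number of inter-unit transfers per
#'   patient-day.
#' @param shift_template roster template, see [default_shift_template()].
#' @param group_mix proportions of the five nurse groups
#'   (rn/lpn/other/student/external); must sum to 1.
#' @param age_dist truncated-normal age spec per department (or one for all):
#'   list with `mean`, `sd`, `min`, `max` in years.
#' @param defect_rates list with `missing_working_hours` (fraction of core
#'   nurses whose working-hours rows are dropped), `outpatient` (fraction of
#'   cases flagged outpatient), `newborn` (fraction of maternity cases that
#'   are healthy newborns).
#' @param icd10_chapter_weights named list per department of chapter-label ->
#'   weight vectors; defaults to a department-typical mix.
#' @param n_outpatient_units number of additional outpatient units that emit
#'   activity rows only (exercised by the inpatient filter).
#' @param activity_mix per nurse-day probabilities of extra non-care activity
#'   rows (administrative, teaching, continuous_education, absence).
#' @param seed integer seed; every simulation operation is deterministic
#'   given the configuration including this seed.
#' @return an object of class `sim_config` (a validated list), with a
#'   `units` tibble (`unit_id`, `department`) attached.
#' @export
#' @examples
#' cfg <- sim_config(departments = list("Internal Medicine" = 2),
#'                   start_date = "2015-01-01", end_date = "2015-01-31")
#' cfg$units
sim_config <- function(departments = list("Internal Medicine" = 2,
                                          "Cardiology & Cardiovascular Surgery" = 2,
                                          "Maternity & Gynecology" = 2),
                       start_date = "2015-01-01",
                       end_date = "2015-03-31",
                       admission_rate = default_admission_profile(),
                       unit_rate_multiplier = NULL,
                       los_dist = list(family = "lognormal",
                                       meanlog = log(3), sdlog = 0.7),
                       transfer_prob = 0.05,
                       shift_template = default_shift_template(),
                       group_mix = c(rn = 0.55, lpn = 0.12, other = 0.13,
                                     student = 0.12, external = 0.08),
                       age_dist = list(mean = 58, sd = 18, min = 0, max = 100),
                       defect_rates = list(missing_working_hours = 0,
                                           outpatient = 0.1, newborn = 0.15),
                       icd10_chapter_weights = NULL,
                       n_outpatient_units = 0,
                       activity_mix = c(administrative = 0.3, teaching = 0.05,
                                        continuous_education = 0.05,
                                        absence = 0.03),
                       seed = 1L) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date)) stop("invalid horizon dates")
  if (end_date < start_date) stop("end_date must be >= start_date")

  departments <- as.list(departments)
  if (length(departments) == 0 || is.null(names(departments)))
    stop("`departments` must be a named list of unit counts")
  n_units <- sum(unlist(departments))
  if (n_units < 1) stop("at least one unit is required")
  units <- tibble::tibble(
    unit_id = sprintf("U%02d", seq_len(n_units)),
    department = rep(names(departments), times = unlist(departments))
  )

  if (is.matrix(admission_rate)) {
    if (!all(dim(admission_rate) == c(24, 7)))
      stop("matrix admission_rate must be 24 x 7 (hour x weekday)")
    rate_mat <- admission_rate
  } else {
    if (length(admission_rate) != 1) stop("admission_rate must be scalar or 24x7 matrix")
    rate_mat <- matrix(admission_rate, 24, 7)
  }
  if (any(is.na(rate_mat)) || any(rate_mat < 0)) stop("admission rates must be >= 0")

  mult <- setNames(rep(1, n_units), units$unit_id)
  if (!is.null(unit_rate_multiplier)) {
    bad <- setdiff(names(unit_rate_multiplier), units$unit_id)
    if (length(bad)) stop("unknown units in unit_rate_multiplier: ",
                          paste(bad, collapse = ", "))
    mult[names(unit_rate_multiplier)] <- unit_rate_multiplier
  }
  if (any(mult < 0)) stop("unit rate multipliers must be >= 0")

  if (!is.null(los_dist$family)) los_dist <- setNames(
    rep(list(los_dist), length(departments)), names(departments))
  for (d in names(los_dist)) {
    if (!los_dist[[d]]$family %in% c("lognormal", "gamma", "exponential"))
      stop("unsupported LOS family: ", los_dist[[d]]$family)
  }

  if (abs(sum(group_mix) - 1) > 1e-9) stop("group_mix must sum to 1")
  if (any(group_mix < 0)) stop("group_mix proportions must be >= 0")
  if (!all(c("rn", "lpn", "other", "student", "external") %in% names(group_mix)))
    stop("group_mix must name all five nurse groups")

  for (sh in shift_template) {
    ss <- parse_clock(sh$start); ee <- parse_clock(sh$end)
    if (is.na(ss) || is.na(ee)) stop("invalid clock time in shift template")
    if (any(c(sh$weekday, sh$weekend) < 0)) stop("staffing levels must be >= 0")
    if (!is.null(sh$break_window) &&
        any(is.na(parse_clock(sh$break_window))))
      stop("invalid break window clock times")
  }

  if (!is.null(age_dist$mean)) age_dist <- setNames(
    rep(list(age_dist), length(departments)), names(departments))

  dr <- utils::modifyList(list(missing_working_hours = 0, outpatient = 0,
                               newborn = 0), as.list(defect_rates))
  if (any(unlist(dr) < 0 | unlist(dr) > 1)) stop("defect rates must be in [0, 1]")

  if (is.null(icd10_chapter_weights)) icd10_chapter_weights <- setNames(
    lapply(names(departments), default_chapter_weights), names(departments))

  if (transfer_prob < 0) stop("transfer_prob must be >= 0")

  structure(list(
    departments = departments, units = units,
    start_date = start_date, end_date = end_date,
    rate_mat = rate_mat, unit_rate_multiplier = mult,
    los_dist = los_dist, transfer_prob = transfer_prob,
    shift_template = shift_template, group_mix = group_mix,
    age_dist = age_dist, defect_rates = dr,
    icd10_chapter_weights = icd10_chapter_weights,
    n_outpatient_units = as.integer(n_outpatient_units),
    activity_mix = activity_mix,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", nrow(x$units), " units / ",
      length(x$departments), " departments, ",
      format(x$start_date), " .. ", format(x$end_date),
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
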