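## Linkage of the staffing-system sheets with the medical discharge sheet:
## the inpatient/care activity filter, the nurse-side and patient-side
## merges, deidentification, and the exclusion funnel that documents every
## stage with counts and percentages.

clock_secs <- function(x) if (is.numeric(x)) x else parse_clock(x)

funnel_add <- function(funnel, stage, metric, n, denom) {
  dplyr::bind_rows(funnel, tibble::tibble(
    stage = stage, metric = metric, n = as.numeric(n),
    denom = as.numeric(denom)))
}

#' Restrict activity data to inpatient direct/indirect care
#'
#' First funnel stage: retains only activity rows recorded on inpatient
#' units with activity type `care`, dropping outpatient units and non-care
#' activities (administrative, teaching, continuous education, absences).
#' Full-row duplicate activity records are removed before any merging.
#' Stage counts (cases, nurses, units before and after) are recorded in the
#' bundle's funnel.
#'
#' @param bundle a `wardflow_bundle` (from [read_sources()] or
#'   [simulate_bundle()]).
#' @return the bundle with filtered `activity` and a `funnel` element.
#' @export
filter_care_activity <- function(bundle) {
  act <- bundle$activity
  n_dup <- nrow(act) - nrow(dplyr::distinct(act))
  act <- dplyr::distinct(act)

  src_cases <- dplyr::n_distinct(act$case_id, na.rm = TRUE)
  src_nurses <- dplyr::n_distinct(act$nurse_id)
  src_units <- dplyr::n_distinct(act$unit_id)

  keep <- act$setting == "inpatient" & act$activity_type == "care"
  act2 <- act[keep, ]

  funnel <- tibble::tibble(stage = character(), metric = character(),
                           n = numeric(), denom = numeric())
  funnel <- funnel_add(funnel, "source", "cases", src_cases, src_cases)
  funnel <- funnel_add(funnel, "source", "nurses", src_nurses, src_nurses)
  funnel <- funnel_add(funnel, "source", "units", src_units, src_units)
  funnel <- funnel_add(funnel, "inpatient_care", "cases",
                       dplyr::n_distinct(act2$case_id, na.rm = TRUE), src_cases)
  funnel <- funnel_add(funnel, "inpatient_care", "nurses",
                       dplyr::n_distinct(act2$nurse_id), src_nurses)
  funnel <- funnel_add(funnel, "inpatient_care", "units",
                       dplyr::n_distinct(act2$unit_id), src_units)

  bundle$activity <- act2
  bundle$funnel <- funnel
  bundle$log <- c(bundle$log, list(duplicate_activity_rows = n_dup))
  bundle
}

#' Nurse-side linkage: shifts and daily presence
#'
#' Joins the filtered care activity with the nurse sheet (qualification
#' group) and the working-hours sheet on nurse, contract and date. Core
#' nurses (groups 1-3) whose care activity on a date has no working-hours
#' rows are excluded *for that date only*, and the excluded person-days are
#' counted. Students and externals (groups 4-5) carry no working hours and
#' are routed to a daily-presence table instead. Contract identifiers are
#' dropped after the join; duplicate working-hours rows (same nurse,
#' contract, date, start) are deduplicated and counted.
#'
#' @param bundle bundle that has passed [filter_care_activity()].
#' @return list with `shifts` (nurse working segments with group and unit),
#'   `daily_presence` (date, unit, group 4-5, count), the updated `funnel`,
#'   and an `exclusions` list.
#' @export
link_nurse_side <- function(bundle) {
  stopifnot(!is.null(bundle$funnel))
  act <- dplyr::inner_join(bundle$activity, bundle$nurses,
                           by = c("nurse_id", "contract_id"))

  core_days <- act |>
    dplyr::filter(.data$group %in% 1:3) |>
    dplyr::distinct(.data$nurse_id, .data$contract_id, .data$unit_id,
                    .data$group, .data$date)

  wh <- bundle$working_hours |>
    dplyr::mutate(start_secs = clock_secs(.data$start_time),
                  end_secs = clock_secs(.data$end_time))
  n_wh <- nrow(wh)
  wh <- dplyr::distinct(wh, .data$nurse_id, .data$contract_id, .data$date,
                        .data$start_secs, .keep_all = TRUE)
  dup_wh <- n_wh - nrow(wh)

  matched <- dplyr::inner_join(
    core_days, wh, by = c("nurse_id", "contract_id", "date"),
    relationship = "many-to-many")
  shifts <- matched |>
    dplyr::mutate(
      start_ts = ts_make(.data$date, .data$start_secs),
      # a segment ending at or before its start runs past midnight
      end_ts = ts_make(.data$date, .data$end_secs +
                         ifelse(.data$end_secs <= .data$start_secs, 86400, 0))) |>
    dplyr::select("nurse_id", "unit_id", "group", "start_ts", "end_ts") |>
    dplyr::arrange(.data$nurse_id, .data$start_ts)

  no_wh <- dplyr::anti_join(core_days, wh,
                            by = c("nurse_id", "contract_id", "date"))
  person_days_total <- nrow(dplyr::distinct(core_days, .data$nurse_id,
                                            .data$date))
  person_days_excl <- nrow(dplyr::distinct(no_wh, .data$nurse_id, .data$date))

  daily_presence <- act |>
    dplyr::filter(.data$group %in% 4:5) |>
    dplyr::distinct(.data$nurse_id, .data$unit_id, .data$group, .data$date) |>
    dplyr::count(.data$date, .data$unit_id, .data$group, name = "count")

  usable <- dplyr::n_distinct(c(
    shifts$nurse_id,
    act$nurse_id[act$group %in% 4:5]))
  denom_nurses <- bundle$funnel$n[bundle$funnel$stage == "inpatient_care" &
                                    bundle$funnel$metric == "nurses"]
  funnel <- funnel_add(bundle$funnel, "working_time", "nurses",
                       usable, denom_nurses)
  funnel <- funnel_add(funnel, "working_time", "person_days_excluded",
                       person_days_excl, person_days_total)

  list(shifts = shifts, daily_presence = daily_presence, funnel = funnel,
       exclusions = list(
         person_days_excluded = person_days_excl,
         nurses_affected = dplyr::n_distinct(no_wh$nurse_id),
         duplicate_working_hours = dup_wh))
}

#' Patient-side linkage: stays and case table
#'
#' Orders the movement events of every case in time and pairs them into
#' per-unit stay intervals: an admission or transfer opens a stay, a
#' transfer or discharge closes it; a transfer's exit and entry share one
#' timestamp. Cases flagged outpatient in the movement data are excluded and
#' counted, as are healthy newborns of the Maternity & Gynecology department
#' (flag in the discharge sheet). Cases whose events cannot be paired (e.g.
#' a transfer before any admission, a discharge before admission, or a
#' missing discharge record) are rejected with a reason.
#'
#' @param bundle bundle that has passed [filter_care_activity()].
#' @param funnel funnel to extend (default the bundle's).
#' @return list with `stays`, `cases`, the updated `funnel`, an
#'   `exclusions` list, and `rejects`.
#' @export
link_patient_side <- function(bundle, funnel = bundle$funnel) {
  stopifnot(!is.null(funnel))
  cases_in <- unique(bundle$activity$case_id)
  cases_in <- cases_in[!is.na(cases_in)]
  denom <- length(cases_in)

  mv <- bundle$movements |>
    dplyr::filter(.data$case_id %in% cases_in) |>
    dplyr::mutate(ts = ts_make(.data$date, clock_secs(.data$time)))

  out_cases <- unique(mv$case_id[mv$setting == "outpatient"])
  mv <- mv[!mv$case_id %in% out_cases, ]

  # deterministic event order; ties broken admission < transfer < discharge
  mv <- mv |>
    dplyr::mutate(prio = match(.data$event,
                               c("admission", "transfer", "discharge"))) |>
    dplyr::arrange(.data$case_id, .data$ts, .data$prio)

  rejects <- list(); stays <- list()
  for (piece in split(mv, mv$case_id)) {
    cid <- piece$case_id[1]
    k <- nrow(piece)
    reason <- NULL
    if (piece$event[1] != "admission") reason <- "first event is not an admission"
    else if (piece$event[k] != "discharge") reason <- "no closing discharge event"
    else if (k > 2 && any(piece$event[2:(k - 1)] != "transfer"))
      reason <- "events cannot be paired"
    else if (piece$ts[k] < piece$ts[1]) reason <- "discharge before admission"
    else if (is.unsorted(as.numeric(piece$ts))) reason <- "events out of order"
    if (!is.null(reason)) {
      rejects[[cid]] <- tibble::tibble(case_id = cid, reason = reason)
      next
    }
    m <- k - 1L # number of stays
    stays[[cid]] <- tibble::tibble(
      case_id = cid,
      unit_id = piece$unit_id[seq_len(m)],
      entry_ts = piece$ts[seq_len(m)],
      exit_ts = piece$ts[seq_len(m) + 1L],
      entry_kind = c("admission", rep("transfer_in", m - 1L)),
      exit_kind = c(rep("transfer_out", m - 1L), "discharge"))
  }
  stays <- if (length(stays)) dplyr::bind_rows(stays) else tibble::tibble(
    case_id = character(), unit_id = character(),
    entry_ts = as.POSIXct(character(), tz = "UTC"),
    exit_ts = as.POSIXct(character(), tz = "UTC"),
    entry_kind = character(), exit_kind = character())
  rejects <- dplyr::bind_rows(rejects)

  dis <- bundle$discharges
  if (is.null(dis$healthy_newborn)) dis$healthy_newborn <- FALSE
  paired_ids <- unique(stays$case_id)
  linked <- dis[dis$case_id %in% paired_ids, ]
  no_record <- setdiff(paired_ids, linked$case_id)
  if (length(no_record)) {
    rejects <- dplyr::bind_rows(rejects, tibble::tibble(
      case_id = no_record, reason = "no medical discharge record"))
  }

  nb_cases <- linked$case_id[linked$healthy_newborn &
                               linked$department == "Maternity & Gynecology"]
  used <- linked[!linked$case_id %in% nb_cases, ]
  stays <- stays[stays$case_id %in% used$case_id, ]

  cases <- used |>
    dplyr::mutate(
      los_days = compute_los(.data$admission_date, .data$discharge_date),
      chapter = icd10_chapter(.data$main_dx)) |>
    dplyr::select("case_id", "department", "age_years", "admission_date",
                  "discharge_date", "los_days", "main_dx", "chapter")

  funnel <- funnel_add(funnel, "patient_side", "outpatient_cases_excluded",
                       length(out_cases), denom)
  funnel <- funnel_add(funnel, "patient_side", "newborn_cases_excluded",
                       length(nb_cases), denom)
  funnel <- funnel_add(funnel, "patient_side", "cases_used",
                       nrow(cases), denom)

  list(stays = stays, cases = cases, funnel = funnel,
       exclusions = list(outpatient = length(out_cases),
                         newborns = length(nb_cases),
                         unpaired = nrow(rejects)),
       rejects = rejects)
}

#' Replace raw identifiers by stable pseudonyms
#'
#' Maps case, nurse and unit identifiers to `Patient1...`, `Nurse1...`,
#' `Unit1...`. Pseudonyms are assigned in sorted order of the raw
#' identifiers, so the same input always yields the same pseudonyms. The
#' mapping is discarded unless `keep_map = TRUE`.
#'
#' @param linked a `wardflow_linked` dataset (see [link_bundle()]).
#' @param keep_map retain the raw-to-pseudonym maps as attribute `id_map`.
#' @return the linked dataset with pseudonymized identifiers.
#' @export
deidentify <- function(linked, keep_map = FALSE) {
  pmap <- function(ids, prefix) {
    u <- sort(unique(ids))
    setNames(paste0(prefix, seq_along(u)), u)
  }
  case_map <- pmap(linked$cases$case_id, "Patient")
  nurse_map <- pmap(linked$shifts$nurse_id, "Nurse")
  unit_map <- pmap(unique(c(linked$stays$unit_id, linked$shifts$unit_id,
                            linked$daily_presence$unit_id)), "Unit")

  linked$cases$case_id <- unname(case_map[linked$cases$case_id])
  linked$stays$case_id <- unname(case_map[linked$stays$case_id])
  linked$stays$unit_id <- unname(unit_map[linked$stays$unit_id])
  linked$shifts$nurse_id <- unname(nurse_map[linked$shifts$nurse_id])
  linked$shifts$unit_id <- unname(unit_map[linked$shifts$unit_id])
  linked$daily_presence$unit_id <- unname(unit_map[linked$daily_presence$unit_id])
  linked$units$unit_id <- unname(unit_map[linked$units$unit_id])
  linked$units <- linked$units[!is.na(linked$units$unit_id), ]
  if (keep_map)
    attr(linked, "id_map") <- list(cases = case_map, nurses = nurse_map,
                                   units = unit_map)
  linked
}

#' Link the two sources end to end
#'
#' Runs [filter_care_activity()], [link_nurse_side()] and
#' [link_patient_side()], infers the unit-to-department map, deidentifies
#' all identifiers, and returns the analysis dataset together with the
#' exclusion funnel and reject reports.
#'
#' @param bundle a `wardflow_bundle`.
#' @param keep_map see [deidentify()].
#' @return object of class `wardflow_linked`: list with `stays`, `shifts`,
#'   `cases`, `daily_presence`, `units` (unit-to-department map), `funnel`,
#'   `rejects` and `exclusions`.
#' @export
#' @examples
#' b <- simulate_bundle(sim_config(end_date = "2015-01-14"))
#' ld <- link_bundle(b)
#' funnel_report(ld)
link_bundle <- function(bundle, keep_map = FALSE) {
  bundle <- filter_care_activity(bundle)
  ns <- link_nurse_side(bundle)
  ps <- link_patient_side(bundle, funnel = ns$funnel)

  # unit -> department: modal department of the cases staying on the unit
  units <- ps$stays |>
    dplyr::left_join(ps$cases[, c("case_id", "department")], by = "case_id") |>
    dplyr::count(.data$unit_id, .data$department) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("unit_id", "department")

  linked <- structure(list(
    stays = ps$stays, shifts = ns$shifts, cases = ps$cases,
    daily_presence = ns$daily_presence, units = units,
    funnel = ps$funnel,
    rejects = dplyr::bind_rows(bundle$rejects, ps$rejects),
    exclusions = c(ns$exclusions, ps$exclusions)
  ), class = "wardflow_linked")
  deidentify(linked, keep_map = keep_map)
}

#' Exclusion funnel with percentages
#'
#' @param x a `wardflow_linked` dataset or a raw funnel tibble
#'   (`stage`, `metric`, `n`, `denom`).
#' @return tibble with `stage`, `metric`, `n`, `denom` and `pct`
#'   (half-up, one decimal; missing when the denominator is zero).
#' @export
funnel_report <- function(x) {
  funnel <- if (inherits(x, "wardflow_linked")) x$funnel else x
  stopifnot(all(c("stage", "metric", "n", "denom") %in% names(funnel)))
  dplyr::mutate(funnel, pct = pct_of(.data$n, .data$denom))
}

#' @export
print.wardflow_linked <- function(x, ...) {
  cat("<wardflow_linked> ", nrow(x$cases), " cases, ",
      dplyr::n_distinct(x$shifts$nurse_id), " nurses, ",
      nrow(x$units), " units\n", sep = "")
  invisible(x)
}
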