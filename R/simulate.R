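## Discrete-event ward simulator. Admissions follow a time-inhomogeneous
## Poisson process on an (hour-of-day x weekday) intensity grid; lengths of
## stay are right-skewed draws; transfers relocate a patient instantaneously
## (the closing transfer-out and the opening transfer-in share one
## timestamp). All event times are continuous (sub-second) so that ties with
## the 30-minute slot lattice are measure-zero.

# truncated normal via inverse CDF
rtnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

draw_los_days <- function(n, spec) {
  x <- switch(spec$family,
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    gamma = rgamma(n, shape = spec$shape, rate = spec$rate),
    exponential = rexp(n, rate = 1 / spec$mean_days)
  )
  pmax(x, 2 / 24) # a stay is at least ~2 h; zero-length stays are not modelled
}

#' Simulate patient flow: admissions, transfers, discharges
#'
#' Draws hospital cases from a time-inhomogeneous Poisson admission process
#' on each unit, assigns each case an age, a length of stay and an ICD-10
#' main diagnosis from its department's distributions, and relocates patients
#' between units with the configured per-patient-day transfer intensity. The
#' hospital episode of each case is thereby split into one `stay` interval
#' per visited unit; a transfer's exit and entry share one timestamp.
#'
#' @param config a [sim_config()].
#' @return list with `cases` (one row per admission episode) and `stays`
#'   (one row per contiguous presence on one unit, with `entry_kind` in
#'   admission/transfer_in and `exit_kind` in discharge/transfer_out).
#'   Deterministic given `config` (including its seed).
#' @export
simulate_patient_flow <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)

  days <- seq(config$start_date, config$end_date, by = "day")
  dow <- day_of_week(days)
  units <- config$units

  # vectorized arrivals: one Poisson draw per unit x day x hour
  grid <- expand.grid(hour = 0:23, day_i = seq_along(days),
                      unit_i = seq_len(nrow(units)))
  lam <- config$rate_mat[cbind(grid$hour + 1L, dow[grid$day_i])] *
    config$unit_rate_multiplier[units$unit_id[grid$unit_i]]
  n_adm <- rpois(nrow(grid), lam)
  idx <- rep.int(seq_len(nrow(grid)), n_adm)

  empty_cases <- tibble::tibble(
    case_id = character(), unit_admit = character(), department = character(),
    admission_ts = as.POSIXct(character(), tz = "UTC"),
    discharge_ts = as.POSIXct(character(), tz = "UTC"),
    los_days = integer(), age_years = numeric(),
    main_dx = character(), chapter = character())
  empty_stays <- tibble::tibble(
    case_id = character(), unit_id = character(), department = character(),
    entry_ts = as.POSIXct(character(), tz = "UTC"),
    exit_ts = as.POSIXct(character(), tz = "UTC"),
    entry_kind = character(), exit_kind = character())
  if (length(idx) == 0) return(list(cases = empty_cases, stays = empty_stays))

  unit_admit <- units$unit_id[grid$unit_i[idx]]
  department <- units$department[grid$unit_i[idx]]
  adm_ts <- ts_make(days[grid$day_i[idx]],
                    grid$hour[idx] * 3600 + runif(length(idx)) * 3600)
  ord <- order(adm_ts)
  unit_admit <- unit_admit[ord]; department <- department[ord]
  adm_ts <- adm_ts[ord]
  n <- length(adm_ts)
  case_id <- sprintf("C%07d", seq_len(n))

  los_cont <- numeric(n); age <- numeric(n); dx <- character(n)
  for (d in names(config$departments)) {
    sel <- department == d
    if (!any(sel)) next
    los_cont[sel] <- draw_los_days(sum(sel), config$los_dist[[d]])
    ad <- config$age_dist[[d]]
    age[sel] <- round(rtnorm(sum(sel), ad$mean, ad$sd, ad$min, ad$max), 1)
    w <- config$icd10_chapter_weights[[d]]
    dx[sel] <- sample_icd10_code(
      sample(names(w), sum(sel), replace = TRUE, prob = w))
  }
  dis_ts <- adm_ts + los_cont * 86400

  cases <- tibble::tibble(
    case_id = case_id, unit_admit = unit_admit, department = department,
    admission_ts = adm_ts, discharge_ts = dis_ts,
    los_days = as.integer(ts_date(dis_ts) - ts_date(adm_ts)),
    age_years = age, main_dx = dx, chapter = icd10_chapter(dx))

  # transfers: Poisson count per case with intensity transfer_prob / patient-day
  n_tr <- if (nrow(units) > 1 && config$transfer_prob > 0)
    rpois(n, config$transfer_prob * los_cont) else integer(n)
  n_tr[los_cont < 0.25] <- 0L # no transfers within very short stays

  simple <- n_tr == 0
  stays <- tibble::tibble(
    case_id = case_id[simple], unit_id = unit_admit[simple],
    entry_ts = adm_ts[simple], exit_ts = dis_ts[simple],
    entry_kind = "admission", exit_kind = "discharge")

  if (any(!simple)) {
    moved <- which(!simple)
    pieces <- lapply(moved, function(i) {
      k <- n_tr[i]
      tt <- sort(adm_ts[i] + runif(k, 0.05, 0.95) * (los_cont[i] * 86400))
      path <- character(k + 1); path[1] <- unit_admit[i]
      for (j in seq_len(k))
        path[j + 1] <- sample(setdiff(units$unit_id, path[j]), 1)
      bounds <- c(adm_ts[i], tt, dis_ts[i])
      tibble::tibble(
        case_id = case_id[i], unit_id = path,
        entry_ts = bounds[seq_len(k + 1)], exit_ts = bounds[seq_len(k + 1) + 1],
        entry_kind = c("admission", rep("transfer_in", k)),
        exit_kind = c(rep("transfer_out", k), "discharge"))
    })
    stays <- dplyr::bind_rows(stays, dplyr::bind_rows(pieces))
  }

  stays <- stays |>
    dplyr::left_join(units, by = "unit_id") |>
    dplyr::arrange(.data$case_id, .data$entry_ts) |>
    dplyr::select("case_id", "unit_id", "department", "entry_ts", "exit_ts",
                  "entry_kind", "exit_kind")

  list(cases = cases, stays = stays)
}

## ---- roster ---------------------------------------------------------------

shift_times_abs <- function(day, sh) {
  s <- parse_clock(sh$start); e <- parse_clock(sh$end)
  start_ts <- ts_make(day, s)
  end_ts <- ts_make(day, e + if (e <= s) 86400 else 0)
  bw <- NULL
  if (!is.null(sh$break_window)) {
    ws <- parse_clock(sh$break_window[1]); we <- parse_clock(sh$break_window[2])
    if (ws < s) ws <- ws + 86400
    if (we <= ws) we <- we + 86400
    bw <- c(ts_make(day, ws), ts_make(day, we))
  }
  list(start = start_ts, end = end_ts, break_window = bw,
       break_minutes = sh$break_minutes %||% 0)
}

#' Simulate the nurse roster
#'
#' Rosters the configured number of nurses per unit, shift and qualification
#' group for every day of the horizon. Break rules split each shift into two
#' working segments. Students and external nurses (groups 4-5) are emitted
#' as daily presence rows only - they carry no working-hours segments,
#' mirroring staffing systems in which these groups are not regular employees
#' and no breakdown of their time allocation exists.
#'
#' @param config a [sim_config()].
#' @return list with `nurses` (nurse_id, contract_id, group 1-5),
#'   `segments` (working intervals of groups 1-3) and `presence`
#'   (daily rows of groups 4-5). Deterministic given `config`.
#' @export
simulate_roster <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed + 1L)

  units <- config$units
  days <- seq(config$start_date, config$end_date, by = "day")
  tmpl <- config$shift_template
  for (sh in tmpl) if (any(c(sh$weekday, sh$weekend) < 0))
    stop("staffing levels must be >= 0")

  nurse_counter <- 0L
  new_nurses <- function(k, group) {
    if (k == 0) return(tibble::tibble(nurse_id = character(),
                                      contract_id = character(),
                                      group = integer()))
    ids <- sprintf("N%05d", nurse_counter + seq_len(k))
    nurse_counter <<- nurse_counter + k
    tibble::tibble(nurse_id = ids, contract_id = paste0("K", substring(ids, 2)),
                   group = as.integer(group))
  }

  nurses <- list(); segments <- list(); presence <- list()
  core_daily <- sum(vapply(tmpl, function(sh) sum(sh$weekday), numeric(1)))

  for (u in seq_len(nrow(units))) {
    uid <- units$unit_id[u]
    # per-group pool large enough to cover the maximum simultaneous demand
    pools <- list()
    for (g in 1:3) {
      lab <- .group_labels[as.character(g)]
      need <- max(vapply(tmpl, function(sh)
        max(sh$weekday[lab] %||% 0, sh$weekend[lab] %||% 0, na.rm = TRUE),
        numeric(1)), 0)
      pool <- new_nurses(ceiling(need * 2) + (need > 0), g)
      pools[[lab]] <- pool
      nurses[[length(nurses) + 1]] <- pool
    }
    # students / externals: presence intensity derived from the group mix
    mix <- config$group_mix
    lam <- core_daily * mix[c("student", "external")] /
      max(sum(mix[c("rn", "lpn", "other")]), 1e-9)
    aux_pools <- list(
      student = new_nurses(max(2 * ceiling(lam[["student"]] + 1), 2), 4L),
      external = new_nurses(max(2 * ceiling(lam[["external"]] + 1), 2), 5L))
    nurses[[length(nurses) + 1]] <- aux_pools$student
    nurses[[length(nurses) + 1]] <- aux_pools$external

    for (di in seq_along(days)) {
      day <- days[di]
      wk <- if (is_weekend(day)) "weekend" else "weekday"
      for (sh in tmpl) {
        lv <- sh[[wk]]
        tm <- shift_times_abs(day, sh)
        for (g in 1:3) {
          lab <- .group_labels[as.character(g)]
          k <- as.integer(lv[lab] %||% 0)
          if (is.na(k) || k == 0) next
          pool <- pools[[lab]]
          chosen <- pool[sample.int(nrow(pool), k), ]
          if (tm$break_minutes > 0 && !is.null(tm$break_window)) {
            dur <- tm$break_minutes * 60
            span <- as.numeric(tm$break_window[2]) - dur -
              as.numeric(tm$break_window[1])
            bstart <- as.numeric(tm$break_window[1]) +
              floor(runif(k) * max(span, 0) / 300) * 300
            seg <- tibble::tibble(
              nurse_id = rep(chosen$nurse_id, 2),
              contract_id = rep(chosen$contract_id, 2),
              unit_id = uid, group = as.integer(g),
              start_ts = c(rep(tm$start, k),
                           as.POSIXct(bstart + dur, tz = "UTC",
                                      origin = "1970-01-01")),
              end_ts = c(as.POSIXct(bstart, tz = "UTC", origin = "1970-01-01"),
                         rep(tm$end, k)))
          } else {
            seg <- tibble::tibble(
              nurse_id = chosen$nurse_id, contract_id = chosen$contract_id,
              unit_id = uid, group = as.integer(g),
              start_ts = tm$start, end_ts = tm$end)
          }
          segments[[length(segments) + 1]] <- seg
        }
      }
      for (lab in c("student", "external")) {
        k <- min(rpois(1, lam[[lab]]), nrow(aux_pools[[lab]]))
        if (k == 0) next
        chosen <- aux_pools[[lab]][sample.int(nrow(aux_pools[[lab]]), k), ]
        presence[[length(presence) + 1]] <- tibble::tibble(
          nurse_id = chosen$nurse_id, contract_id = chosen$contract_id,
          unit_id = uid, group = chosen$group, date = day)
      }
    }
  }

  nurses <- dplyr::bind_rows(nurses)
  segments <- if (length(segments)) dplyr::bind_rows(segments) else
    tibble::tibble(nurse_id = character(), contract_id = character(),
                   unit_id = character(), group = integer(),
                   start_ts = as.POSIXct(character(), tz = "UTC"),
                   end_ts = as.POSIXct(character(), tz = "UTC"))
  presence <- if (length(presence)) dplyr::bind_rows(presence) else
    tibble::tibble(nurse_id = character(), contract_id = character(),
                   unit_id = character(), group = integer(),
                   date = as.Date(character()))
  list(nurses = nurses, segments = dplyr::arrange(segments, .data$nurse_id,
                                                  .data$start_ts),
       presence = presence)
}

## ---- activity -------------------------------------------------------------

# expand stays to one row per calendar day the stay touches
stay_days <- function(stays) {
  if (nrow(stays) == 0)
    return(tibble::tibble(case_id = character(), unit_id = character(),
                          date = as.Date(character())))
  first <- ts_date(stays$entry_ts)
  last <- ts_date(stays$exit_ts - 1e-6) # exit exactly at midnight ends the day before
  last <- pmax(last, first)
  k <- as.integer(last - first) + 1L
  tibble::tibble(
    case_id = rep(stays$case_id, k),
    unit_id = rep(stays$unit_id, k),
    date = as.Date(unlist(mapply(function(f, n) f + 0:(n - 1), first, k,
                                 SIMPLIFY = FALSE)),
                   origin = "1970-01-01"))
}

#' Simulate nurse activity records
#'
#' Links every on-duty nurse to patients present on her unit that day through
#' direct/indirect-care activity rows, and adds administrative, teaching,
#' continuous-education and absence rows at the configured per-nurse-day
#' probabilities. Students and externals contribute care rows on their
#' presence days. Optional outpatient units contribute activity-only rows
#' that the downstream inpatient filter must remove.
#'
#' @param cases,stays output of [simulate_patient_flow()].
#' @param segments,presence output of [simulate_roster()].
#' @param config a [sim_config()].
#' @return list with `activity` (the activity sheet) and `op_nurses`
#'   (roster rows of outpatient-unit nurses, needed for key integrity).
#'   Deterministic given `config`.
#' @export
simulate_activity <- function(cases, stays, segments, config,
                              presence = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed + 2L)
  presence <- presence %||% tibble::tibble(
    nurse_id = character(), contract_id = character(), unit_id = character(),
    group = integer(), date = as.Date(character()))

  sd_tab <- stay_days(stays)
  nurse_days <- dplyr::distinct(
    segments, .data$nurse_id, .data$contract_id, .data$unit_id,
    date = ts_date(.data$start_ts))

  care <- tibble::tibble(nurse_id = character(), contract_id = character(),
                         case_id = character(), unit_id = character(),
                         date = as.Date(character()))
  if (nrow(sd_tab) && nrow(nurse_days)) {
    pairs <- dplyr::inner_join(sd_tab, nurse_days, by = c("unit_id", "date"),
                               relationship = "many-to-many")
    if (nrow(pairs)) {
      # each patient-day is documented by 1-2 of the nurses on duty ...
      care <- pairs |>
        dplyr::group_by(.data$case_id, .data$date) |>
        dplyr::slice_sample(n = 2) |>
        dplyr::filter(dplyr::row_number() <= sample(1:2, 1)) |>
        dplyr::ungroup() |>
        dplyr::select("nurse_id", "contract_id", "case_id", "unit_id", "date")
      # ... and every on-duty nurse documents care for at least one patient
      # present on her unit that day (if any), so that no worked day is
      # silent in the activity sheet
      uncovered <- dplyr::anti_join(
        nurse_days, care,
        by = c("nurse_id", "contract_id", "unit_id", "date"))
      if (nrow(uncovered)) {
        fill <- uncovered |>
          dplyr::inner_join(sd_tab, by = c("unit_id", "date"),
                            relationship = "many-to-many") |>
          dplyr::group_by(.data$nurse_id, .data$contract_id, .data$date) |>
          dplyr::slice_sample(n = 1) |>
          dplyr::ungroup() |>
          dplyr::select("nurse_id", "contract_id", "case_id", "unit_id",
                        "date")
        care <- dplyr::bind_rows(care, fill)
      }
    }
  }

  aux_care <- tibble::tibble()
  if (nrow(presence) && nrow(sd_tab)) {
    aux_care <- presence |>
      dplyr::inner_join(sd_tab, by = c("unit_id", "date"),
                        relationship = "many-to-many") |>
      dplyr::group_by(.data$nurse_id, .data$date) |>
      dplyr::slice_sample(n = 1) |>
      dplyr::ungroup() |>
      dplyr::select("nurse_id", "contract_id", "case_id", "unit_id", "date")
  }

  activity <- dplyr::bind_rows(care, aux_care) |>
    dplyr::mutate(activity_type = "care", setting = "inpatient")

  # non-care rows per core nurse-day
  extra <- list()
  for (tp in names(config$activity_mix)) {
    p <- config$activity_mix[[tp]]
    if (p <= 0 || nrow(nurse_days) == 0) next
    hit <- runif(nrow(nurse_days)) < p
    if (!any(hit)) next
    extra[[tp]] <- nurse_days[hit, ] |>
      dplyr::mutate(case_id = NA_character_, activity_type = tp,
                    setting = "inpatient")
  }
  activity <- dplyr::bind_rows(activity, dplyr::bind_rows(extra))

  # outpatient units: activity-only rows with their own nurses and cases
  op_nurses <- tibble::tibble(nurse_id = character(),
                              contract_id = character(), group = integer())
  if (config$n_outpatient_units > 0) {
    days <- seq(config$start_date, config$end_date, by = "day")
    op <- list()
    for (i in seq_len(config$n_outpatient_units)) {
      ids <- sprintf("NOP%02d_%02d", i, 1:3)
      op_nurses <- dplyr::bind_rows(op_nurses, tibble::tibble(
        nurse_id = ids, contract_id = sub("^N", "K", ids),
        group = c(1L, 1L, 3L)))
      n_per_day <- rpois(length(days), 8)
      tot <- sum(n_per_day)
      if (tot == 0) next
      op[[i]] <- tibble::tibble(
        nurse_id = sample(ids, tot, replace = TRUE),
        case_id = sprintf("COP%02d_%06d", i, seq_len(tot)),
        unit_id = sprintf("OU%02d", i),
        date = rep(days, n_per_day),
        activity_type = "care", setting = "outpatient") |>
        dplyr::left_join(op_nurses, by = "nurse_id") |>
        dplyr::select("nurse_id", "contract_id", "case_id", "unit_id",
                      "date", "activity_type", "setting")
    }
    activity <- dplyr::bind_rows(activity, dplyr::bind_rows(op))
  }

  list(activity = dplyr::arrange(activity, .data$date, .data$unit_id,
                                 .data$nurse_id),
       op_nurses = op_nurses)
}

## ---- bundle assembly ------------------------------------------------------

#' Simulate a complete linked pair of data sources
#'
#' Runs patient flow, roster and activity simulation and assembles the five
#' staffing-system sheets (activity, nurses, working hours, patient
#' movements) plus the medical discharge sheet, applying the configured
#' data-quality defects: a fraction of core nurses lose all working-hours
#' rows, a fraction of cases is flagged outpatient (present in movement and
#' activity data but absent from discharge data), and a fraction of
#' maternity cases are healthy newborns carrying a flag in the discharge
#' sheet. The generating truth (stays, shift segments, cases with flags) is
#' returned alongside for oracle comparisons.
#'
#' @param config a [sim_config()].
#' @return an object of class `wardflow_bundle`: a list with `activity`,
#'   `nurses`, `working_hours`, `movements`, `discharges`, `truth`
#'   and `config`.
#' @export
#' @examples
#' cfg <- sim_config(departments = list("Internal Medicine" = 1),
#'                   end_date = "2015-01-14", seed = 7)
#' b <- simulate_bundle(cfg)
#' names(b)
simulate_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  flow <- simulate_patient_flow(config)
  roster <- simulate_roster(config)
  act <- simulate_activity(flow$cases, flow$stays, roster$segments, config,
                           presence = roster$presence)

  withr::local_seed(config$seed + 3L)
  cases <- flow$cases
  dr <- config$defect_rates
  n <- nrow(cases)
  cases$outpatient <- if (n) runif(n) < dr$outpatient else logical(0)
  maternity <- cases$department == "Maternity & Gynecology"
  cases$healthy_newborn <- maternity & runif(max(n, 1))[seq_len(n)] < dr$newborn
  cases$healthy_newborn <- cases$healthy_newborn & !cases$outpatient
  if (any(cases$healthy_newborn)) {
    nb <- cases$healthy_newborn
    cases$age_years[nb] <- 0
    cases$main_dx[nb] <- "Z38.0"
    cases$chapter[nb] <- icd10_chapter("Z38.0")
  }

  # presence rows of groups 4-5 are represented in the activity sheet only;
  # nurse records list every nurse, incl. outpatient-unit staff
  nurses <- dplyr::bind_rows(roster$nurses, act$op_nurses)

  wh <- roster$segments
  if (dr$missing_working_hours > 0 && nrow(wh)) {
    core_ids <- unique(wh$nurse_id)
    drop_ids <- core_ids[runif(length(core_ids)) < dr$missing_working_hours]
    wh <- wh[!wh$nurse_id %in% drop_ids, ]
  }
  working_hours <- tibble::tibble(
    nurse_id = wh$nurse_id, contract_id = wh$contract_id,
    date = ts_date(wh$start_ts),
    start_time = format_clock(as.numeric(wh$start_ts) -
                                as.numeric(ts_make(ts_date(wh$start_ts)))),
    end_time = format_clock(as.numeric(wh$end_ts) -
                              as.numeric(ts_make(ts_date(wh$end_ts)))))

  stays <- flow$stays
  setting <- setNames(ifelse(cases$outpatient, "outpatient", "inpatient"),
                      cases$case_id)
  mv_entry <- stays[stays$entry_kind == "admission", ]
  mv_tr <- stays[stays$entry_kind == "transfer_in", ]
  mv_exit <- stays[stays$exit_kind == "discharge", ]
  movements <- dplyr::bind_rows(
    tibble::tibble(case_id = mv_entry$case_id, unit_id = mv_entry$unit_id,
                   event = "admission", ts = mv_entry$entry_ts),
    tibble::tibble(case_id = mv_tr$case_id, unit_id = mv_tr$unit_id,
                   event = "transfer", ts = mv_tr$entry_ts),
    tibble::tibble(case_id = mv_exit$case_id, unit_id = mv_exit$unit_id,
                   event = "discharge", ts = mv_exit$exit_ts)) |>
    dplyr::arrange(.data$case_id, .data$ts) |>
    dplyr::mutate(
      date = ts_date(.data$ts),
      time = format_clock(as.numeric(.data$ts) -
                            as.numeric(ts_make(ts_date(.data$ts)))),
      setting = unname(setting[.data$case_id])) |>
    dplyr::select("case_id", "unit_id", "event", "date", "time", "setting")

  discharges <- cases[!cases$outpatient, ] |>
    dplyr::transmute(.data$case_id, .data$age_years,
                     admission_date = ts_date(.data$admission_ts),
                     discharge_date = ts_date(.data$discharge_ts),
                     main_dx = .data$main_dx, department = .data$department,
                     healthy_newborn = .data$healthy_newborn)

  structure(list(
    activity = act$activity, nurses = nurses,
    working_hours = working_hours, movements = movements,
    discharges = discharges,
    truth = list(cases = cases, stays = stays,
                 segments = roster$segments, presence = roster$presence),
    config = config
  ), class = "wardflow_bundle")
}

#' @export
print.wardflow_bundle <- function(x, ...) {
  cat("<wardflow_bundle>\n",
      "  activity:      ", nrow(x$activity), " rows\n",
      "  nurses:        ", nrow(x$nurses), " rows\n",
      "  working_hours: ", nrow(x$working_hours), " rows\n",
      "  movements:     ", nrow(x$movements), " rows\n",
      "  discharges:    ", nrow(x$discharges), " rows\n", sep = "")
  invisible(x)
}
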