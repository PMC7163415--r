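# Shared fixtures: small configurations and independent brute-force oracles.
# Oracles deliberately use naive per-slot scans, independent of the
# cumulative-count algorithm inside the package.

tiny_cfg <- function(..., seed = 42) {
  sim_config(
    departments = list("Internal Medicine" = 1, "Maternity & Gynecology" = 1),
    start_date = "2015-01-05", end_date = "2015-01-18",
    seed = seed, ...)
}

# half-open membership counted by direct comparison at every slot instant
brute_force_counts <- function(start_ts, end_ts, slot_times) {
  vapply(as.numeric(slot_times), function(t)
    sum(as.numeric(start_ts) <= t & t < as.numeric(end_ts)), numeric(1))
}

# direct tally of events into [t, t + interval) windows
brute_force_event_tally <- function(ts, slot_times, interval_minutes) {
  v <- as.numeric(slot_times); step <- interval_minutes * 60
  vapply(v, function(t) sum(as.numeric(ts) >= t & as.numeric(ts) < t + step),
         numeric(1))
}

rand_stays <- function(n, units, start_date, n_days, seed) {
  withr::with_seed(seed, {
    t0 <- as.numeric(as.POSIXct(as.character(start_date), tz = "UTC"))
    s <- t0 + runif(n, -0.5, n_days) * 86400
    e <- s + runif(n, 0.01, 4) * 86400
    tibble::tibble(
      case_id = sprintf("C%04d", seq_len(n)),
      unit_id = sample(units, n, replace = TRUE),
      entry_ts = as.POSIXct(s, tz = "UTC", origin = "1970-01-01"),
      exit_ts = as.POSIXct(e, tz = "UTC", origin = "1970-01-01"),
      entry_kind = sample(c("admission", "transfer_in"), n, TRUE),
      exit_kind = sample(c("discharge", "transfer_out"), n, TRUE))
  })
}

rand_segments <- function(n, units, start_date, n_days, seed) {
  withr::with_seed(seed, {
    t0 <- as.numeric(as.POSIXct(as.character(start_date), tz = "UTC"))
    s <- t0 + runif(n, 0, n_days) * 86400
    e <- s + runif(n, 0.5, 10) * 3600
    tibble::tibble(
      nurse_id = sprintf("N%04d", seq_len(n)),
      unit_id = sample(units, n, replace = TRUE),
      group = sample(1:3, n, replace = TRUE),
      start_ts = as.POSIXct(s, tz = "UTC", origin = "1970-01-01"),
      end_ts = as.POSIXct(e, tz = "UTC", origin = "1970-01-01"))
  })
}

# minimal bundle for patient-side linkage tests, movement rows given as
# (case, unit, event, "YYYY-MM-DD", "HH:MM") strings
manual_patient_bundle <- function(movements, discharges) {
  act <- tibble::tibble(
    nurse_id = "N1", contract_id = "K1",
    case_id = unique(movements$case_id),
    unit_id = "U1", date = as.Date("2015-01-01"),
    activity_type = "care", setting = "inpatient")
  list(activity = act, movements = movements, discharges = discharges,
       funnel = tibble::tibble(stage = character(), metric = character(),
                               n = numeric(), denom = numeric()))
}
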