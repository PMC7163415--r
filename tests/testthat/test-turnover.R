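test_that("events are assigned to the half-open slot window containing them", {
  g <- build_slot_grid("U1", "2015-01-01", "2015-01-01", 30)
  stays <- tibble::tibble(
    case_id = "A", unit_id = "U1",
    entry_ts = as.POSIXct("2015-01-01 09:15:00", tz = "UTC"),
    exit_ts = as.POSIXct("2015-01-01 17:29:59", tz = "UTC"),
    entry_kind = "admission", exit_kind = "discharge")
  ev <- count_events(stays, g)
  lab <- format(ev$ts, "%H:%M", tz = "UTC")
  expect_identical(lab[ev$n_admissions == 1], "09:00")
  expect_identical(lab[ev$n_discharges == 1], "17:00")
  expect_identical(sum(ev$n_admissions), 1L)
  expect_identical(sum(ev$n_transfers_in) + sum(ev$n_transfers_out), 0L)
})

test_that("one transfer produces exactly one out and one in event", {
  g <- build_slot_grid(c("U1", "U2"), "2015-01-01", "2015-01-02", 30)
  tts <- as.POSIXct("2015-01-01 14:10:00", tz = "UTC")
  stays <- tibble::tibble(
    case_id = "A", unit_id = c("U1", "U2"),
    entry_ts = c(as.POSIXct("2015-01-01 08:00:00", tz = "UTC"), tts),
    exit_ts = c(tts, as.POSIXct("2015-01-02 10:00:00", tz = "UTC")),
    entry_kind = c("admission", "transfer_in"),
    exit_kind = c("transfer_out", "discharge"))
  ev <- count_events(stays, g)
  expect_identical(sum(ev$n_transfers_out), 1L)
  expect_identical(sum(ev$n_transfers_in), 1L)
  expect_identical(ev$unit_id[ev$n_transfers_out == 1], "U1")
  expect_identical(ev$unit_id[ev$n_transfers_in == 1], "U2")
  expect_identical(ev$ts[ev$n_transfers_in == 1],
                   ev$ts[ev$n_transfers_out == 1])
})

test_that("per-slot event counts equal a brute-force tally", {
  g <- build_slot_grid(c("A", "B"), "2015-03-01", "2015-03-07", 30)
  stays <- rand_stays(250, c("A", "B"), "2015-03-01", 7, seed = 9)
  ev <- count_events(stays, g)
  for (u in c("A", "B")) {
    su <- stays[stays$unit_id == u, ]
    eu <- ev[ev$unit_id == u, ]
    expect_equal(as.numeric(eu$n_admissions),
                 brute_force_event_tally(
                   su$entry_ts[su$entry_kind == "admission"],
                   g$slot_times, 30))
    expect_equal(as.numeric(eu$n_discharges),
                 brute_force_event_tally(
                   su$exit_ts[su$exit_kind == "discharge"],
                   g$slot_times, 30))
    expect_equal(as.numeric(eu$n_transfers_in),
                 brute_force_event_tally(
                   su$entry_ts[su$entry_kind == "transfer_in"],
                   g$slot_times, 30))
    expect_equal(as.numeric(eu$n_transfers_out),
                 brute_force_event_tally(
                   su$exit_ts[su$exit_kind == "transfer_out"],
                   g$slot_times, 30))
  }
  # events outside the grid are excluded and logged
  all_ev <- as.numeric(c(stays$entry_ts, stays$exit_ts))
  lo <- as.numeric(g$slot_times[1])
  hi <- as.numeric(g$slot_times[length(g$slot_times)]) + 1800
  expect_identical(attr(ev, "n_excluded"),
                   as.integer(sum(all_ev < lo | all_ev >= hi)))
})

test_that("normalization divides by the census and preserves counts at zero", {
  g <- build_slot_grid("U1", "2015-01-01", "2015-01-01", 30)
  ev <- count_events(tibble::tibble(
    case_id = c("A", "B"), unit_id = "U1",
    entry_ts = as.POSIXct("2015-01-01 09:05:00", tz = "UTC") + c(0, 60),
    exit_ts = as.POSIXct("2015-01-01 22:00:00", tz = "UTC") + c(0, 60),
    entry_kind = "admission", exit_kind = "discharge"), g)
  census <- count_patients(tibble::tibble(
    case_id = sprintf("P%02d", 1:20), unit_id = "U1",
    entry_ts = as.POSIXct("2015-01-01 00:00:01", tz = "UTC"),
    exit_ts = as.POSIXct("2015-01-01 23:59:59", tz = "UTC")), g)
  tp <- normalize_turnover(ev, census)
  lab <- format(tp$ts, "%H:%M", tz = "UTC")
  expect_equal(tp$r_admissions[lab == "09:00"], 2 / 20)
  # zero census at 00:00 (entries at 00:00:01): missing ratio, count kept
  ev0 <- count_events(tibble::tibble(
    case_id = "Q", unit_id = "U1",
    entry_ts = as.POSIXct("2015-01-01 00:10:00", tz = "UTC"),
    exit_ts = as.POSIXct("2015-01-01 05:00:00", tz = "UTC"),
    entry_kind = "admission", exit_kind = "discharge"), g)
  census0 <- count_patients(tibble::tibble(
    case_id = "Q", unit_id = "U1",
    entry_ts = as.POSIXct("2015-01-01 00:10:00", tz = "UTC"),
    exit_ts = as.POSIXct("2015-01-01 05:00:00", tz = "UTC")), g)
  tp0 <- normalize_turnover(ev0, census0)
  expect_identical(tp0$n_admissions[lab == "00:00"], 1L)
  expect_true(is.na(tp0$r_admissions[lab == "00:00"]))
  # grid mismatch is an error
  g2 <- build_slot_grid("U1", "2015-01-01", "2015-01-02", 30)
  expect_error(normalize_turnover(ev, count_patients(tibble::tibble(
    case_id = character(), unit_id = character(),
    entry_ts = as.POSIXct(character(), tz = "UTC"),
    exit_ts = as.POSIXct(character(), tz = "UTC")), g2)), "grid")
})

test_that("department profiles average unit ratios with signed exits", {
  res <- run_pipeline(tiny_cfg(seed = 17))
  pr <- res$profiles
  expect_true(all(pr$r_discharges <= 0, na.rm = TRUE))
  expect_true(all(pr$r_transfers_out <= 0, na.rm = TRUE))
  expect_true(all(pr$r_admissions >= 0, na.rm = TRUE))

  # arithmetic oracle: recompute one department x daytype x slot cell
  um <- res$linked$units
  tp <- dplyr::inner_join(res$turnover, um, by = "unit_id")
  tp$daytype <- ifelse(format(tp$ts, "%u") %in% c("6", "7"),
                       "weekend", "weekday")
  tp$slot <- format(tp$ts, "%H:%M", tz = "UTC")
  cell <- pr[which(!is.na(pr$r_admissions) & pr$r_admissions > 0)[1], ]
  sub <- tp[tp$department == cell$department & tp$daytype == cell$daytype &
              tp$slot == cell$slot, ]
  unit_means <- tapply(sub$r_admissions, sub$unit_id,
                       function(x) if (all(is.na(x))) NA else mean(x, na.rm = TRUE))
  expect_equal(cell$r_admissions, mean(unit_means, na.rm = TRUE))
})

test_that("hospital-wide transfer flows balance on every bundle", {
  for (seed in c(3, 11, 27)) {
    res <- run_pipeline(tiny_cfg(seed = seed, transfer_prob = 0.15))
    expect_identical(sum(res$events$n_transfers_in),
                     sum(res$events$n_transfers_out))
    expect_gt(sum(res$events$n_transfers_in), 0L)
  }
})

test_that("no nocturnal events means exactly zero night turnover", {
  g <- build_slot_grid("U1", "2015-01-05", "2015-01-11", 30)
  # events confined to 08:00-18:00
  stays <- withr::with_seed(31, {
    n <- 60
    d <- sample(0:6, n, TRUE)
    tibble::tibble(
      case_id = sprintf("C%03d", 1:n), unit_id = "U1",
      entry_ts = as.POSIXct("2015-01-05", tz = "UTC") + d * 86400 +
        runif(n, 8, 15) * 3600,
      exit_ts = as.POSIXct("2015-01-05", tz = "UTC") + d * 86400 +
        runif(n, 15.5, 18) * 3600,
      entry_kind = "admission", exit_kind = "discharge")
  })
  ev <- count_events(stays, g)
  hr <- as.integer(format(ev$ts, "%H", tz = "UTC"))
  night <- hr >= 22 | hr < 6
  tot <- ev$n_admissions + ev$n_discharges + ev$n_transfers_in +
    ev$n_transfers_out
  expect_true(all(tot[night] == 0L))
  expect_gt(sum(tot[!night]), 0L)
})

test_that("census first differences equal entries minus exits per slot", {
  res <- run_pipeline(tiny_cfg(seed = 13, transfer_prob = 0.1))
  cen <- res$census
  ev <- res$events
  for (u in unique(cen$unit_id)) {
    n <- cen$n_patients[cen$unit_id == u]
    eu <- ev[ev$unit_id == u, ]
    entries <- eu$n_admissions + eu$n_transfers_in
    exits <- eu$n_discharges + eu$n_transfers_out
    k <- length(n)
    expect_identical(diff(n), (entries - exits)[-k])
  }
})
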