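test_that("empty sheets read back as an empty bundle without rejects", {
  d <- withr::local_tempdir()
  sch <- wardflow_schema()
  for (nm in names(sch)) {
    empty <- as.data.frame(setNames(
      rep(list(character(0)), nrow(sch[[nm]])), sch[[nm]]$column))
    readr::write_csv(empty, file.path(d, paste0(nm, ".csv")))
  }
  b <- read_sources(d)
  expect_s3_class(b, "wardflow_bundle")
  for (nm in names(sch)) expect_identical(nrow(b[[nm]]), 0L)
  expect_identical(nrow(b$rejects), 0L)
})

test_that("malformed rows land in the reject report, good rows survive", {
  b <- simulate_bundle(tiny_cfg())
  d <- withr::local_tempdir()
  write_bundle(b, d)
  wh <- readr::read_csv(file.path(d, "working_hours.csv"),
                        col_types = readr::cols(.default = "c"))
  wh$start_time[1] <- "25:99"
  mv <- readr::read_csv(file.path(d, "movements.csv"),
                        col_types = readr::cols(.default = "c"))
  mv$time[2] <- "not a time"
  readr::write_csv(wh, file.path(d, "working_hours.csv"))
  readr::write_csv(mv, file.path(d, "movements.csv"))

  b2 <- read_sources(d)
  expect_identical(nrow(b2$rejects), 2L)
  expect_setequal(b2$rejects$sheet, c("working_hours", "movements"))
  expect_match(b2$rejects$reason, "time", all = TRUE)
  expect_identical(nrow(b2$working_hours), nrow(wh) - 1L)
  expect_identical(nrow(b2$movements), nrow(mv) - 1L)
})

test_that("a missing required column is a hard error naming the column", {
  b <- simulate_bundle(tiny_cfg())
  d <- withr::local_tempdir()
  write_bundle(b, d)
  act <- readr::read_csv(file.path(d, "activity.csv"),
                         col_types = readr::cols(.default = "c"))
  act$activity_type <- NULL
  readr::write_csv(act, file.path(d, "activity.csv"))
  expect_error(read_sources(d), "activity_type")
})

test_that("the write-read round trip preserves the record sets", {
  b <- simulate_bundle(tiny_cfg(n_outpatient_units = 1))
  d <- withr::local_tempdir()
  write_bundle(b, d)
  b2 <- read_sources(d)
  expect_identical(nrow(b2$rejects), 0L)
  expect_identical(as.data.frame(b2$activity[order(b2$activity$nurse_id,
                                                   b2$activity$date,
                                                   b2$activity$case_id), ]),
                   as.data.frame(b$activity[order(b$activity$nurse_id,
                                                  b$activity$date,
                                                  b$activity$case_id), ]))
  expect_identical(as.data.frame(dplyr::arrange(b2$nurses, nurse_id,
                                                contract_id)),
                   as.data.frame(dplyr::arrange(b$nurses, nurse_id,
                                                contract_id)))
  expect_identical(nrow(b2$movements), nrow(b$movements))
  expect_identical(nrow(b2$working_hours), nrow(b$working_hours))
  expect_equal(as.data.frame(b2$discharges),
               as.data.frame(b$discharges))
})

test_that("movement events pair into stays; a transfer shares one timestamp", {
  mv <- tibble::tibble(
    case_id = c("A", "A", "B", "B", "B"),
    unit_id = c("U1", "U1", "U1", "U2", "U2"),
    event = c("admission", "discharge", "admission", "transfer", "discharge"),
    date = as.Date(c("2015-01-01", "2015-01-03", "2015-01-01", "2015-01-02",
                     "2015-01-04")),
    time = c("09:10", "11:00", "08:00", "14:30", "10:00"),
    setting = "inpatient")
  dis <- tibble::tibble(
    case_id = c("A", "B"), age_years = c(60, 70),
    admission_date = as.Date("2015-01-01"),
    discharge_date = as.Date(c("2015-01-03", "2015-01-04")),
    main_dx = c("I21.0", "C34.1"), department = "Internal Medicine",
    healthy_newborn = FALSE)
  ps <- link_patient_side(manual_patient_bundle(mv, dis))

  expect_identical(nrow(ps$rejects), 0L)
  a <- ps$stays[ps$stays$case_id == "A", ]
  expect_identical(nrow(a), 1L)
  expect_identical(a$entry_kind, "admission")
  expect_identical(a$exit_kind, "discharge")
  b <- ps$stays[ps$stays$case_id == "B", ]
  expect_identical(nrow(b), 2L)
  expect_identical(b$unit_id, c("U1", "U2"))
  expect_identical(b$exit_ts[1], b$entry_ts[2]) # instantaneous transfer
  expect_identical(b$exit_kind[1], "transfer_out")
  expect_identical(b$entry_kind[2], "transfer_in")
})

test_that("unpairable event sequences are rejected with a reason", {
  mv <- tibble::tibble(
    case_id = c("X", "X", "Y", "Y", "Z"),
    unit_id = "U1",
    event = c("admission", "admission", "admission", "discharge", "transfer"),
    date = as.Date(c("2015-01-01", "2015-01-02", "2015-01-05", "2015-01-02",
                     "2015-01-01")),
    time = c("08:00", "08:00", "08:00", "08:00", "08:00"),
    setting = "inpatient")
  dis <- tibble::tibble(case_id = c("X", "Y", "Z"), age_years = 50,
                        admission_date = as.Date("2015-01-01"),
                        discharge_date = as.Date("2015-01-06"),
                        main_dx = "I21.0", department = "Internal Medicine",
                        healthy_newborn = FALSE)
  ps <- link_patient_side(manual_patient_bundle(mv, dis))
  expect_identical(nrow(ps$stays), 0L)
  expect_identical(nrow(ps$rejects), 3L)
  expect_gt(length(unique(ps$rejects$reason)), 1L)
})

test_that("nurse-days without working time are excluded for that day only", {
  act <- tibble::tibble(
    nurse_id = "N1", contract_id = "K1", case_id = c("A", "B"),
    unit_id = "U1", date = as.Date(c("2015-01-01", "2015-01-02")),
    activity_type = "care", setting = "inpatient")
  nur <- tibble::tibble(nurse_id = "N1", contract_id = "K1", group = 1L)
  wh <- tibble::tibble(nurse_id = "N1", contract_id = "K1",
                       date = as.Date("2015-01-01"),
                       start_time = "07:00", end_time = "15:30")
  bundle <- list(activity = act, nurses = nur, working_hours = wh,
                 funnel = tibble::tibble(stage = "inpatient_care",
                                         metric = "nurses", n = 1,
                                         denom = 1))
  ns <- link_nurse_side(bundle)
  expect_identical(nrow(ns$shifts), 1L)
  expect_identical(as.Date(ns$shifts$start_ts, tz = "UTC"),
                   as.Date("2015-01-01"))
  expect_identical(ns$exclusions$person_days_excluded, 1L)
  expect_identical(ns$exclusions$nurses_affected, 1L)
  expect_false("contract_id" %in% names(ns$shifts))
})

test_that("midnight-crossing working hours end on the next day", {
  act <- tibble::tibble(nurse_id = "N1", contract_id = "K1", case_id = "A",
                        unit_id = "U1", date = as.Date("2015-01-01"),
                        activity_type = "care", setting = "inpatient")
  nur <- tibble::tibble(nurse_id = "N1", contract_id = "K1", group = 1L)
  wh <- tibble::tibble(nurse_id = "N1", contract_id = "K1",
                       date = as.Date("2015-01-01"),
                       start_time = "23:00", end_time = "07:15")
  ns <- link_nurse_side(list(activity = act, nurses = nur, working_hours = wh,
                             funnel = tibble::tibble(stage = "inpatient_care",
                                                     metric = "nurses",
                                                     n = 1, denom = 1)))
  expect_identical(format(ns$shifts$end_ts, "%Y-%m-%d %H:%M", tz = "UTC"),
                   "2015-01-02 07:15")
})

test_that("group 4-5 nurses route to daily presence, never to shifts", {
  linked <- link_bundle(simulate_bundle(tiny_cfg()))
  expect_true(all(linked$shifts$group %in% 1:3))
  expect_true(all(linked$daily_presence$group %in% 4:5))
  expect_gt(nrow(linked$daily_presence), 0)
})

test_that("deidentification is stable and leaves no raw identifier behind", {
  b <- simulate_bundle(tiny_cfg())
  l1 <- link_bundle(b)
  l2 <- link_bundle(b)
  expect_identical(as.data.frame(l1$cases), as.data.frame(l2$cases))
  expect_identical(as.data.frame(l1$shifts), as.data.frame(l2$shifts))

  raw_ids <- unique(c(b$activity$nurse_id, b$activity$case_id,
                      b$activity$unit_id, b$activity$contract_id,
                      b$nurses$contract_id))
  raw_ids <- raw_ids[!is.na(raw_ids)]
  for (tab in list(l1$cases, l1$stays, l1$shifts, l1$daily_presence,
                   l1$units)) {
    for (col in names(tab)[vapply(tab, is.character, TRUE)])
      expect_length(intersect(tab[[col]], raw_ids), 0)
  }
  # pseudonym spaces have the same cardinality as the raw id spaces
  expect_identical(dplyr::n_distinct(l1$cases$case_id),
                   dplyr::n_distinct(b$discharges$case_id[
                     !b$discharges$healthy_newborn]))
  map <- attr(link_bundle(b, keep_map = TRUE), "id_map")
  expect_named(map, c("cases", "nurses", "units"))
})

test_that("funnel counts are monotone and percentages well-formed", {
  linked <- link_bundle(simulate_bundle(tiny_cfg(n_outpatient_units = 1)))
  fr <- funnel_report(linked)
  cases <- fr[fr$metric == "cases", ]
  used <- fr[fr$metric == "cases_used", ]
  expect_true(all(diff(cases$n) <= 0))
  expect_lte(used$n, min(cases$n))
  expect_true(all(fr$pct[fr$denom > 0] >= 0 & fr$pct[fr$denom > 0] <= 100))
  expect_true(is.na(pct_of(0, 0)))
})

test_that("stay durations partition each hospital episode exactly", {
  b <- simulate_bundle(tiny_cfg(defect_rates = list(
    missing_working_hours = 0, outpatient = 0, newborn = 0)))
  st <- b$truth$stays
  dur <- tapply(as.numeric(st$exit_ts) - as.numeric(st$entry_ts),
                st$case_id, sum)
  cs <- b$truth$cases
  episode <- setNames(as.numeric(cs$discharge_ts) -
                        as.numeric(cs$admission_ts), cs$case_id)
  expect_equal(as.vector(dur[names(episode)]), unname(episode),
               tolerance = 1e-9)
})

test_that("zero-defect bundles recover the generating truth exactly", {
  b <- simulate_bundle(tiny_cfg(defect_rates = list(
    missing_working_hours = 0, outpatient = 0, newborn = 0)))
  d <- withr::local_tempdir()
  write_bundle(b, d)
  bf <- filter_care_activity(read_sources(d))
  ps <- link_patient_side(bf)
  ns <- link_nurse_side(bf)

  tr <- dplyr::arrange(b$truth$stays, case_id, entry_ts)
  rec <- dplyr::arrange(ps$stays, case_id, entry_ts)
  expect_identical(rec$case_id, tr$case_id)
  expect_identical(rec$unit_id, tr$unit_id)
  expect_identical(rec$entry_kind, tr$entry_kind)
  expect_equal(as.numeric(rec$entry_ts), as.numeric(tr$entry_ts),
               tolerance = 1e-3)
  expect_equal(as.numeric(rec$exit_ts), as.numeric(tr$exit_ts),
               tolerance = 1e-3)

  trs <- dplyr::arrange(b$truth$segments, nurse_id, start_ts)
  recs <- dplyr::arrange(ns$shifts, nurse_id, start_ts)
  expect_identical(recs$nurse_id, trs$nurse_id)
  expect_identical(recs$unit_id, trs$unit_id)
  expect_identical(recs$group, trs$group)
  expect_equal(as.numeric(recs$start_ts), as.numeric(trs$start_ts),
               tolerance = 1e-3)
  expect_equal(as.numeric(recs$end_ts), as.numeric(trs$end_ts),
               tolerance = 1e-3)
})
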