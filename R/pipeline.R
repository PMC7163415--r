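#' Run the full supply-demand analysis pipeline
#'
#' Simulates a bundle (or accepts one), links the two sources, expands them
#' onto the slot lattice, and computes ratio series, extreme-mismatch
#' summaries, key-timepoint summaries, turnover points and department
#' profiles, plus the descriptive overview.
#'
#' @param config a [sim_config()]; ignored when `bundle` is supplied.
#' @param bundle optionally, an existing `wardflow_bundle`.
#' @param interval_minutes slot length of the analysis lattice.
#' @param reference_slot daily reference slot for patients/day/unit.
#' @return list with `bundle`, `linked`, `grid`, `census`, `ratios`,
#'   `thresholds`, `key_timepoints`, `events`, `turnover`, `profiles`,
#'   `overview`, `daily_presence_summary` and `funnel`.
#' @export
#' @examples
#' res <- run_pipeline(sim_config(end_date = "2015-01-14", seed = 3))
#' res$funnel
run_pipeline <- function(config = sim_config(), bundle = NULL,
                         interval_minutes = 30, reference_slot = "12:00") {
  if (is.null(bundle)) bundle <- simulate_bundle(config)
  cfg <- bundle$config %||% config
  linked <- link_bundle(bundle)

  grid <- build_slot_grid(
    units = unique(c(linked$stays$unit_id, linked$shifts$unit_id)),
    start_date = cfg$start_date, end_date = cfg$end_date,
    interval_minutes = interval_minutes)

  census <- build_census(linked$stays, linked$shifts, grid)
  ratios <- compute_ratios(census)
  thresholds <- compute_thresholds(ratios)
  key_tp <- key_timepoint_summary(ratios, linked$units)
  events <- count_events(linked$stays, grid)
  turnover <- normalize_turnover(events, census)
  profiles <- aggregate_profiles(turnover, linked$units)
  overview <- department_overview(linked, census,
                                  reference_slot = reference_slot)
  dps <- daily_presence_summary(linked$daily_presence, grid$days)

  list(bundle = bundle, linked = linked, grid = grid, census = census,
       ratios = ratios, thresholds = thresholds, key_timepoints = key_tp,
       events = events, turnover = turnover, profiles = profiles,
       overview = overview, daily_presence_summary = dps,
       funnel = funnel_report(linked))
}
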