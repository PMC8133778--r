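# Shared synthetic sessions, built once per test run and cached. Sizes are
# kept small (5-7 min sessions, 40 cells) so the full suite stays fast
# while preserving the occupancy and event structure the tests rely on.

.session_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .session_cache)) assign(key, expr, envir = .session_cache)
  get(key, envir = .session_cache)
}

epm_config <- function(seed = 101, ...) {
  args <- utils::modifyList(list(seed = seed, session_length = 300,
                                 n_cells = 40, snr = 5, n_freeze = 3,
                                 n_head_dip = 3), list(...))
  do.call(simulation_config, args)
}

rat_config <- function(seed = 101, ...) {
  args <- utils::modifyList(list(seed = seed, session_length = 400,
                                 n_cells = 40, snr = 5, n_freeze = 3,
                                 n_approach = 3, n_escape = 3,
                                 n_rat_movement = 3), list(...))
  do.call(simulation_config, args)
}

epm_session <- function() cached("epm", simulate_session(assay_geometry("EPM"), epm_config()))
rat_session <- function() cached("rat", simulate_session(assay_geometry("RAT"), rat_config()))
toy_session <- function() cached("toy", simulate_session(assay_geometry("TOY"), rat_config(seed = 103)))

# z-scored traces + behavior channels on the neural clock for one session
processed_session <- function(session, key = NULL) {
  build <- function() {
    kin <- compute_kinematics(session$pose)
    zones <- assign_zones(session$pose)
    geom <- session$geometry
    events <- if (geom$assay_kind == "EPM")
      combine_intervals(detect_freeze(kin), detect_head_dips(session$pose, zones))
    else
      combine_intervals(detect_freeze(kin), detect_approach_escape(kin),
                        detect_rat_movements(kin))
    sc <- avoidance_approach_score(session$pose, events, geom)
    beh <- data.frame(zone = zones, score = sc$score, speed = kin$speed)
    if (geom$assay_kind == "EPM") beh$location_index <- sc$location_index
    al <- align_timebases(zscore_traces(session$traces), beh,
                          fps = session$pose$fps)
    list(traces = al$traces, behavior = al$behavior, events = events,
         kin = kin, zones = zones)
  }
  if (is.null(key)) build() else cached(key, build())
}

truth_categories <- function(session, cell_ids) {
  session$truth$cell_category[match(cell_ids,
                                    paste0("cell_", seq_along(session$truth$cell_category)))]
}

# onset agreement in frames, with rounding slack
onset_errors <- function(truth_tbl, det_tbl, label, fps = 30) {
  tt <- truth_tbl[truth_tbl$label == label, ]
  dd <- det_tbl[det_tbl$label == label, ]
  if (!nrow(tt) || !nrow(dd)) return(Inf)
  vapply(tt$onset, function(o) min(abs(dd$onset - o)) * fps, numeric(1))
}
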