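#' Synthetic-session configuration
#'
#' Parameters of the synthetic generator. Defaults reflect the recording
#' conditions of the assays the package targets: 30 frames/s behavioral
#' video, 7.5 Hz neural sampling, GCaMP6s-like 2 s calcium decay, 20 min
#' sessions (shortened here to 10 min, which preserves all occupancy and
#' event statistics at half the cost), and a co-registered cell fraction of
#' 0.44 (the observed cross-assay registration yield is ~44%).
#'
#' `snr` is defined as the tuned-cell response amplitude divided by the
#' additive noise SD. `artifact_amplitude` > 0 injects a slow multiplicative
#' bleaching ramp shared across all cells, before any z-scoring.
#'
#' @param n_cells number of simulated cells.
#' @param frac_open,frac_closed,frac_neither planted ensemble fractions;
#'   must sum to 1.
#' @param snr tuning amplitude / noise SD; must be > 0 when simulating
#'   activity.
#' @param calcium_decay_tau single-exponential calcium kernel decay, seconds.
#' @param session_length session duration, seconds.
#' @param behavior_fps,neural_hz behavioral and neural sampling rates; their
#'   ratio must be an integer (30 / 7.5 = 4).
#' @param seed integer; fully determines the generated session.
#' @param coregistration_frac fraction of cells co-registered across assays.
#' @param artifact_amplitude relative amplitude of the shared bleaching ramp.
#' @param n_freeze,n_head_dip,n_approach,n_escape,n_rat_movement planted
#'   event counts (head dips apply to the EPM; approach/escape/rat movements
#'   to the rat arena).
#' @param baseline_rate,tuning_strength baseline and tuned response
#'   amplitude of the simulated rate, dF/F units.
#' @param travel_speed_cms background locomotion speed, cm/s; kept below the
#'   3 cm/s approach/escape threshold so only planted bouts cross it.
#' @param pose_jitter_cm per-frame Gaussian keypoint jitter (0 = noiseless
#'   kinematics).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 60, frac_open = 0.25,
                              frac_closed = 0.25, frac_neither = 0.5,
                              snr = 5, calcium_decay_tau = 2,
                              session_length = 600, behavior_fps = 30,
                              neural_hz = 7.5, seed = 1,
                              coregistration_frac = 0.44,
                              artifact_amplitude = 0,
                              n_freeze = 4, n_head_dip = 4, n_approach = 4,
                              n_escape = 4, n_rat_movement = 3,
                              baseline_rate = 0.1, tuning_strength = 1,
                              travel_speed_cms = 2.5, pose_jitter_cm = 0) {
  if (abs(frac_open + frac_closed + frac_neither - 1) > 1e-9)
    stop("ensemble fractions must sum to 1")
  ratio <- behavior_fps / neural_hz
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("behavior_fps must be an integer multiple of neural_hz")
  stopifnot(n_cells >= 1, session_length > 0, calcium_decay_tau > 0,
            coregistration_frac > 0, coregistration_frac <= 1,
            artifact_amplitude >= 0, travel_speed_cms > 0.25,
            travel_speed_cms < 3, pose_jitter_cm >= 0)
  seed <- as.integer(seed)
  structure(list(n_cells = as.integer(n_cells), frac_open = frac_open,
                 frac_closed = frac_closed, frac_neither = frac_neither,
                 snr = snr, calcium_decay_tau = calcium_decay_tau,
                 session_length = session_length,
                 behavior_fps = behavior_fps, neural_hz = neural_hz,
                 seed = seed, coregistration_frac = coregistration_frac,
                 artifact_amplitude = artifact_amplitude,
                 n_freeze = as.integer(n_freeze),
                 n_head_dip = as.integer(n_head_dip),
                 n_approach = as.integer(n_approach),
                 n_escape = as.integer(n_escape),
                 n_rat_movement = as.integer(n_rat_movement),
                 baseline_rate = baseline_rate,
                 tuning_strength = tuning_strength,
                 travel_speed_cms = travel_speed_cms,
                 pose_jitter_cm = pose_jitter_cm),
            class = "simulation_config")
}

# Planted ensemble sizes; rounding remainder absorbed by the neither group.
#' @noRd
planted_categories <- function(config) {
  n <- config$n_cells
  n_open <- round(config$frac_open * n)
  n_closed <- round(config$frac_closed * n)
  if (n_open + n_closed > n) n_closed <- n - n_open
  c(rep("open", n_open), rep("closed", n_closed),
    rep("neither", n - n_open - n_closed))
}
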