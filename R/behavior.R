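# Pose-derived kinematics and behavior classification.
#
# All detectors operate on the smoothed kinematics returned by
# compute_kinematics(); thresholds are the field's: freezing when head and
# tailbase speeds are below 0.25 cm/s for at least 0.33 s, approach/escape
# when the mouse moves toward/away from the rat above 3 cm/s, rat movements
# above the session's 99.5th speed percentile with a 5.33 s refractory rule.

#' Per-frame kinematics from a pose track
#'
#' Computes head, tailbase and body-centroid speeds (smoothed with a
#' centered moving average), and in the rat arena the distance to the rat,
#' the signed radial velocity (negative toward the rat), the head-to-rat
#' angle, and the raw (unsmoothed) rat speed used for rat-movement
#' detection.
#'
#' @param pose a [pose_track()].
#' @param smooth_s smoothing window in seconds (0.33 by default, matched to
#'   the freeze-duration scale; suppresses tracker jitter).
#' @return data.frame of class `kinematic_series` with one row per frame;
#'   attributes `fps` and `assay`.
#' @export
compute_kinematics <- function(pose, smooth_s = 0.33) {
  stopifnot(inherits(pose, "pose_track"))
  d <- pose$data
  n <- nrow(d)
  if (n < 2) stop("need at least 2 frames to compute kinematics")
  fps <- pose$fps
  w <- max(1L, round(smooth_s * fps))
  head_x <- (d$nose_x + d$ear_l_x + d$ear_r_x) / 3
  head_y <- (d$nose_y + d$ear_l_y + d$ear_r_y) / 3
  cen_x <- (d$nose_x + d$ear_l_x + d$ear_r_x + d$tailbase_x) / 4
  cen_y <- (d$nose_y + d$ear_l_y + d$ear_r_y + d$tailbase_y) / 4
  spd <- function(x, y) {
    s <- c(NA, sqrt(diff(x)^2 + diff(y)^2)) * fps
    s[1] <- s[2]
    moving_average(s, w)
  }
  out <- data.frame(speed_head = spd(head_x, head_y),
                    speed_tail = spd(d$tailbase_x, d$tailbase_y),
                    speed = spd(cen_x, cen_y),
                    mouse_x = cen_x, mouse_y = cen_y)
  if (pose$geometry$assay_kind %in% c("RAT", "TOY")) {
    dist_rat <- sqrt((cen_x - d$rat_x)^2 + (cen_y - d$rat_y)^2)
    rad <- c(NA, diff(dist_rat)) * fps
    rad[1] <- rad[2]
    ear_mx <- (d$ear_l_x + d$ear_r_x) / 2
    ear_my <- (d$ear_l_y + d$ear_r_y) / 2
    ang <- (atan2(d$rat_y - head_y, d$rat_x - head_x) -
              atan2(d$nose_y - ear_my, d$nose_x - ear_mx)) * 180 / pi
    rat_spd <- c(NA, sqrt(diff(d$rat_x)^2 + diff(d$rat_y)^2)) * fps
    rat_spd[1] <- rat_spd[2]
    out$dist_rat <- dist_rat
    out$radial_velocity <- moving_average(rad, w)
    out$angle_to_rat <- ang %% 360
    out$rat_speed <- rat_spd            # raw: burst onsets must stay sharp
    out$rat_x <- d$rat_x
    out$rat_y <- d$rat_y
  }
  structure(out, fps = fps, assay = pose$geometry$assay_kind,
            class = c("kinematic_series", "data.frame"))
}

# Sign of the displacement of `x` over a centered window; displacements
# below min_disp hold the previous direction (near-stationary frames carry
# no direction information of their own).
#' @noRd
binarize_direction <- function(x, fps, window_s = 0.33, min_disp = 0.1) {
  n <- length(x)
  h <- max(1L, round(window_s * fps / 2))
  idx <- seq_len(n)
  disp <- x[pmin(n, idx + h)] - x[pmax(1L, idx - h)]
  dir <- ifelse(disp > min_disp, 1L, ifelse(disp < -min_disp, -1L, NA_integer_))
  if (is.na(dir[1])) dir[1] <- 1L
  for (t in which(is.na(dir))) if (t > 1L) dir[t] <- dir[t - 1L]
  dir
}

#' @noRd
runs_to_intervals <- function(flag, fps, min_dur, label, meta = NULL) {
  r <- true_runs(flag)
  if (nrow(r)) r <- r[(r$end - r$start + 1L) / fps >= min_dur - 1e-9, , drop = FALSE]
  behavior_intervals(rep(label, nrow(r)), (r$start - 1L) / fps, r$end / fps,
                     meta = meta)
}

#' Detect freezing
#'
#' Maximal runs in which head *and* tailbase speeds are both below
#' `speed_thresh` for at least `min_dur` seconds.
#'
#' @param kin a `kinematic_series`.
#' @param speed_thresh cm/s; default 0.25.
#' @param min_dur seconds; default 0.33.
#' @return [behavior_intervals()] with label `freeze`.
#' @export
detect_freeze <- function(kin, speed_thresh = 0.25, min_dur = 0.33) {
  fps <- attr(kin, "fps")
  runs_to_intervals(kin$speed_head < speed_thresh & kin$speed_tail < speed_thresh,
                    fps, min_dur, "freeze")
}

#' Detect approach and escape bouts (rat arena)
#'
#' Approach: the mouse moves toward the rat above `speed_thresh`; escape:
#' away, same threshold. Direction is the sign of the distance-to-rat
#' displacement over a 0.33 s window (held when nearly stationary).
#'
#' @inheritParams detect_freeze
#' @param speed_thresh cm/s; default 3.
#' @param min_dur minimum bout duration, seconds.
#' @return [behavior_intervals()] with labels `approach` and `escape`.
#' @export
detect_approach_escape <- function(kin, speed_thresh = 3, min_dur = 0.33) {
  if (is.null(kin$dist_rat)) stop("approach/escape detection requires a rat-arena session")
  fps <- attr(kin, "fps")
  dir <- binarize_direction(kin$dist_rat, fps)
  fast <- kin$speed > speed_thresh
  app <- runs_to_intervals(fast & dir < 0, fps, min_dur, "approach")
  esc <- runs_to_intervals(fast & dir > 0, fps, min_dur, "escape")
  out <- rbind(app, esc)
  out <- out[order(out$onset), ]
  class(out) <- c("behavior_intervals", "data.frame")
  out
}

#' Detect prominent rat movements
#'
#' Onsets where the rat's (raw) speed exceeds the session's
#' `percentile`-th speed percentile; of events within `refractory_s` of a
#' kept event, only the first is used. Each kept event is annotated with the
#' direction angle of the rat's movement relative to the mouse position at
#' onset (0 degrees = toward the mouse's initial position).
#'
#' @param kin a `kinematic_series` from a rat-arena session.
#' @param percentile speed percentile defining "prominent"; default 0.995.
#' @param refractory_s merge window, seconds; default 5.33.
#' @return [behavior_intervals()] with label `rat_movement` and meta column
#'   `angle` (degrees in \[0, 360)).
#' @export
detect_rat_movements <- function(kin, percentile = 0.995, refractory_s = 5.33) {
  if (is.null(kin$rat_speed)) stop("rat-movement detection requires rat keypoints")
  fps <- attr(kin, "fps")
  thr <- stats::quantile(kin$rat_speed, percentile, na.rm = TRUE, names = FALSE)
  r <- true_runs(kin$rat_speed > thr)
  if (!nrow(r)) return(behavior_intervals())
  keep <- logical(nrow(r))
  last_kept <- -Inf
  for (i in seq_len(nrow(r))) {
    onset <- (r$start[i] - 1L) / fps
    if (onset - last_kept >= refractory_s) { keep[i] <- TRUE; last_kept <- onset }
  }
  r <- r[keep, , drop = FALSE]
  ang <- vapply(seq_len(nrow(r)), function(i) {
    t0 <- r$start[i]
    t1 <- min(nrow(kin), t0 + 10L)
    mv <- c(kin$rat_x[t1] - kin$rat_x[max(1L, t0 - 1L)],
            kin$rat_y[t1] - kin$rat_y[max(1L, t0 - 1L)])
    to_mouse <- c(kin$mouse_x[t0] - kin$rat_x[max(1L, t0 - 1L)],
                  kin$mouse_y[t0] - kin$rat_y[max(1L, t0 - 1L)])
    ((atan2(mv[2], mv[1]) - atan2(to_mouse[2], to_mouse[1])) * 180 / pi) %% 360
  }, numeric(1))
  behavior_intervals(rep("rat_movement", nrow(r)), (r$start - 1L) / fps,
                     r$end / fps, meta = data.frame(angle = ang))
}

#' Detect head dips (EPM)
#'
#' Frames where the nose lies outside the open-arm boundary (beyond the
#' lateral edges or the arm end) while the body centroid is inside an open
#' arm; runs of at least `min_dur` seconds become head dips. The detection
#' rule is a geometric surrogate for manual scoring and is configurable.
#'
#' @param pose a [pose_track()] from an EPM session.
#' @param zones per-frame zone labels from [assign_zones()].
#' @param min_dur minimum duration, seconds; default 0.2.
#' @return [behavior_intervals()] with label `head_dip`.
#' @export
detect_head_dips <- function(pose, zones, min_dur = 0.2) {
  g <- pose$geometry
  if (g$assay_kind != "EPM") stop("head dips are defined for the EPM only")
  d <- pose$data
  w2 <- g$arm_width / 2
  he <- epm_half_extent(g)
  in_open <- zones %in% c("open1", "open2")
  nose_out <- (abs(d$nose_y) > w2 | abs(d$nose_x) > he)
  runs_to_intervals(in_open & nose_out, pose$fps, min_dur, "head_dip")
}

#' Assign spatial zones
#'
#' EPM: open/closed arm or center-square label per frame, from the body
#' centroid. Rat arena: `safe` in the left `safe_zone_fraction` of the
#' arena by x position, `threatening` within `threat_radius_cm` of the rat
#' (14 cm or less, inclusive), else `middle`.
#'
#' @param pose a [pose_track()].
#' @param geometry an [assay_geometry()]; defaults to the pose's.
#' @param tol tolerance (cm) before an out-of-arena point is an error.
#' @return character vector, one label per frame.
#' @export
assign_zones <- function(pose, geometry = pose$geometry, tol = 1) {
  d <- pose$data
  cen_x <- (d$nose_x + d$ear_l_x + d$ear_r_x + d$tailbase_x) / 4
  cen_y <- (d$nose_y + d$ear_l_y + d$ear_r_y + d$tailbase_y) / 4
  if (geometry$assay_kind == "EPM") {
    w2 <- geometry$arm_width / 2
    he <- epm_half_extent(geometry)
    if (any(pmin(abs(cen_x), abs(cen_y)) > w2 + tol) ||
        any(pmax(abs(cen_x), abs(cen_y)) > he + tol))
      stop("pose coordinates outside the maze beyond tolerance")
    ifelse(abs(cen_x) > w2 & abs(cen_y) <= w2 + tol,
           ifelse(cen_x > 0, "open1", "open2"),
           ifelse(abs(cen_y) > w2 & abs(cen_x) <= w2 + tol,
                  ifelse(cen_y > 0, "closed1", "closed2"), "center"))
  } else {
    L <- geometry$arena_length; W <- geometry$arena_width
    if (any(cen_x < -tol | cen_x > L + tol | cen_y < -tol | cen_y > W + tol))
      stop("pose coordinates outside the arena beyond tolerance")
    d_rat <- sqrt((cen_x - d$rat_x)^2 + (cen_y - d$rat_y)^2)
    ifelse(cen_x <= geometry$safe_zone_fraction * L, "safe",
           ifelse(d_rat <= geometry$threat_radius_cm, "threatening", "middle"))
  }
}

#' EPM location index
#'
#' Maze coordinates are normalized so open-arm ends map to x = +/-1 and
#' closed-arm ends to y = +/-1; the location index is |x| - |y|, close to 1
#' at the end of an open arm, 0 at the center, -1 at the end of a closed
#' arm.
#'
#' @param pose a [pose_track()] from an EPM session (or a data.frame with
#'   `centroid_x`/`centroid_y`-equivalent keypoint columns).
#' @param geometry an [assay_geometry()].
#' @return data.frame with per-frame `x_norm`, `y_norm`, `abs_x`, `abs_y`
#'   and `location_index`.
#' @export
epm_location_index <- function(pose, geometry = pose$geometry) {
  if (geometry$assay_kind != "EPM") stop("location index is defined for the EPM")
  d <- pose$data
  cen_x <- (d$nose_x + d$ear_l_x + d$ear_r_x + d$tailbase_x) / 4
  cen_y <- (d$nose_y + d$ear_l_y + d$ear_r_y + d$tailbase_y) / 4
  he <- epm_half_extent(geometry)
  x_norm <- clip(cen_x / he, -1, 1)
  y_norm <- clip(cen_y / he, -1, 1)
  data.frame(x_norm = x_norm, y_norm = y_norm,
             abs_x = abs(x_norm), abs_y = abs(y_norm),
             location_index = abs(x_norm) - abs(y_norm))
}

#' Avoidance/approach score
#'
#' Continuous per-frame score in \[-1, 1\] combining distance from safety,
#' movement direction, freezing and head dips. Distance from safety is the
#' distance from the safe wall (rat arena, normalized to \[0, 1\]) or the
#' geodesic distance from the nearest closed-arm end along the arm axes
#' through the center (EPM, normalized to \[0, 0.9\]). While moving toward
#' the threat the score is distance-to-safety x (+1); while moving away it
#' is \[1 - distance-to-safety\] x (-1). Freeze frames are forced to the
#' minimum score of -1; EPM head-dip frames are multiplied by 1.11, so a
#' head dip at the end of an open arm yields the maximum score of 1.
#'
#' @param pose a [pose_track()].
#' @param intervals [behavior_intervals()] with detected freezes (and, for
#'   the EPM, head dips).
#' @param geometry an [assay_geometry()].
#' @return data.frame with per-frame `dist_safety`, `direction` (+1 toward
#'   threat), and `score`; EPM output also carries `abs_x`, `abs_y` and
#'   `location_index`.
#' @export
avoidance_approach_score <- function(pose, intervals, geometry = pose$geometry) {
  d <- pose$data
  fps <- pose$fps
  n <- nrow(d)
  cen_x <- (d$nose_x + d$ear_l_x + d$ear_r_x + d$tailbase_x) / 4
  cen_y <- (d$nose_y + d$ear_l_y + d$ear_r_y + d$tailbase_y) / 4
  if (geometry$assay_kind == "EPM") {
    he <- epm_half_extent(geometry)
    d_raw <- he + abs(cen_x) - abs(cen_y)        # geodesic from closed-arm end
    dist_safety <- clip(0.9 * d_raw / (2 * he), 0, 0.9)
    direction <- binarize_direction(d_raw, fps)
  } else {
    dist_safety <- clip(cen_x / geometry$arena_length, 0, 1)
    d_rat <- sqrt((cen_x - d$rat_x)^2 + (cen_y - d$rat_y)^2)
    direction <- -binarize_direction(d_rat, fps)  # toward rat = +1
  }
  score <- ifelse(direction > 0, dist_safety, -(1 - dist_safety))
  if (geometry$assay_kind == "EPM") {
    dips <- interval_indicator(intervals, n, fps, "head_dip")
    score[dips] <- score[dips] * 1.11
  }
  frz <- interval_indicator(intervals, n, fps, "freeze")
  score[frz] <- -1
  score <- clip(score, -1, 1)
  out <- data.frame(dist_safety = dist_safety, direction = direction,
                    score = score)
  if (geometry$assay_kind == "EPM")
    out <- cbind(out, epm_location_index(pose, geometry)[, c("abs_x", "abs_y", "location_index")])
  out
}
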