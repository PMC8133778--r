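# Synthetic session generator.
#
# Trajectories are waypoint walks (closed-arm dwell bias on the EPM,
# safe-side bias in the rat arena) with planted behavioral events spliced in
# as scripted speed profiles. Event onsets are made well-defined by using
# linear speed ramps: the true (noiseless) kinematics cross the detection
# thresholds (0.25 cm/s for freezing, 3 cm/s for approach/escape) at an
# exact frame, and a centered moving average preserves crossings of a linear
# ramp, so downstream detectors can be held to frame-level onset recovery.
# Background locomotion always stays in (0.25, 3) cm/s so only planted bouts
# cross either threshold.

# ---- scripted speed profiles (cm/s, per frame at 30 fps) -----------------

#' @noRd
freeze_speed_profile <- function(s0, dur_frames) {
  c(seq(s0, 1, length.out = 8), rep(1, 5),
    seq(1, 0, length.out = 31)[-1],
    rep(0, dur_frames),
    seq(0, 1, length.out = 31)[-1], rep(1, 5))
}

#' @noRd
dash_speed_profile <- function(s0, dur_frames, peak = 6) {
  c(seq(s0, 1.5, length.out = 8), rep(1.5, 5),
    seq(1.5, peak, length.out = 31)[-1],
    rep(peak, dur_frames),
    seq(peak, 1.5, length.out = 31)[-1], rep(1.5, 5))
}

# ---- EPM skeleton routing ------------------------------------------------

# One step of length step_len along the plus-maze skeleton toward target.
#' @noRd
epm_route_step <- function(p, target, step_len) {
  on_x <- function(q) abs(q[2]) < 1e-9
  on_y <- function(q) abs(q[1]) < 1e-9
  same_branch <- (on_x(p) && on_x(target) && sign(p[1]) * sign(target[1]) >= 0) ||
    (on_y(p) && on_y(target) && sign(p[2]) * sign(target[2]) >= 0)
  if (same_branch) {
    d <- target - p
    len <- sqrt(sum(d^2))
    if (len <= step_len) return(target)
    return(p + d / len * step_len)
  }
  d0 <- sqrt(sum(p^2))
  if (d0 <= step_len) {                       # pass through the center
    rem <- step_len - d0
    len <- sqrt(sum(target^2))
    if (len <= rem) return(target)
    return(target / len * rem)
  }
  p - p / d0 * step_len
}

#' @noRd
epm_skeleton_dist <- function(p, target) {
  same_branch <- (abs(p[2]) < 1e-9 && abs(target[2]) < 1e-9 &&
                    sign(p[1]) * sign(target[1]) >= 0) ||
    (abs(p[1]) < 1e-9 && abs(target[1]) < 1e-9 &&
       sign(p[2]) * sign(target[2]) >= 0)
  if (same_branch) sqrt(sum((p - target)^2))
  else sqrt(sum(p^2)) + sqrt(sum(target^2))
}

# Waypoint menu with closed-arm dwell bias (EPM) or safe-side bias (RAT).
#' @noRd
sample_waypoint <- function(geometry) {
  if (geometry$assay_kind == "EPM") {
    he <- epm_half_extent(geometry) - 3
    pts <- list(c(0, he), c(0, -he), c(0, he / 2), c(0, -he / 2),   # closed
                c(he, 0), c(-he, 0), c(he / 2, 0), c(-he / 2, 0),   # open
                c(0, 0))
    probs <- c(.22, .22, .1, .1, .08, .08, .045, .045, .11)
    pts[[sample.int(length(pts), 1, prob = probs)]]
  } else {
    L <- geometry$arena_length; W <- geometry$arena_width
    mode <- sample.int(3L, 1, prob = c(.4, .3, .3))
    if (mode == 1L)      c(stats::runif(1, 3, 0.18 * L), stats::runif(1, 3, W - 3))
    else if (mode == 2L) c(stats::runif(1, 0.25 * L, 0.7 * L), stats::runif(1, 3, W - 3))
    else                 c(stats::runif(1, L - 13, L - 8), stats::runif(1, W / 2 - 3, W / 2 + 3))
  }
}

#' Simulate a behavioral session
#'
#' Generates a pose track (mouse keypoints, plus rat/toy position in the rat
#' arena) together with planted ground truth: the event table, the per-frame
#' approach/avoid/neutral state sequence, zone occupancy and the planted
#' per-cell ensemble categories.
#'
#' Ground-truth event times are derived from the true, noise-free kinematics
#' by the field's threshold definitions (freeze: speed < 0.25 cm/s; approach
#' and escape: speed > 3 cm/s toward/away from the rat; head dip: nose
#' beyond the open-arm edge while the body is in an open arm), so the table
#' states exactly where the constructed motion satisfies each definition.
#'
#' @param geometry an [assay_geometry()].
#' @param config a [simulation_config()]; `config$seed` fully determines the
#'   output.
#' @return list with elements `pose` ([pose_track()]) and `truth` (class
#'   `ground_truth`: `cell_category`, `state_sequence`, `zone_sequence`,
#'   `planted_event_table`, plus bookkeeping fields).
#' @export
simulate_behavior_session <- function(geometry, config) {
  stopifnot(inherits(geometry, "assay_geometry"),
            inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_behavior_session_impl(geometry, config))
}

#' @noRd
simulate_behavior_session_impl <- function(geometry, config) {
  fps <- config$behavior_fps
  n <- round(config$session_length * fps)
  kind <- geometry$assay_kind
  is_epm <- kind == "EPM"
  travel <- config$travel_speed_cms
  dt <- 1 / fps

  # ---- plant the mouse-event agenda -------------------------------------
  ev_labels <- c(rep("freeze", config$n_freeze),
                 if (is_epm) rep("head_dip", config$n_head_dip),
                 if (!is_epm) c(rep("approach", config$n_approach),
                                rep("escape", config$n_escape)))
  if (length(ev_labels)) ev_labels <- sample(ev_labels)
  n_ev <- length(ev_labels)
  # steering lead before each event: long enough to reach any start point
  # at the assay's background speed cap (8 cm/s EPM, 2.8 cm/s rat arena)
  lead_s <- if (is_epm) 18 else 25
  if (n_ev > 0) {
    spacing <- (config$session_length - 2 * lead_s) / n_ev
    if (spacing < lead_s + 8)
      stop("session too short for the requested number of planted events")
    slots <- round((lead_s + spacing * (seq_len(n_ev) - 1) +
                      stats::runif(n_ev, 0.35 * spacing, 0.55 * spacing)) * fps)
  } else slots <- integer()

  home <- rat_home(geometry)
  ev_start <- lapply(seq_len(n_ev), function(i) {
    switch(ev_labels[i],
           freeze = NULL,                              # anywhere
           head_dip = {
             s <- sample(c(-1, 1), 1)
             c(s * (epm_half_extent(geometry) - 11), 0)
           },
           approach = home + 25 * c(cos(pi + stats::runif(1, -0.2, 0.2)),
                                    sin(pi + stats::runif(1, -0.2, 0.2))),
           escape = home + 10.5 * c(cos(pi + stats::runif(1, -0.25, 0.25)),
                                    sin(pi + stats::runif(1, -0.25, 0.25))))
  })

  # ---- frame loop --------------------------------------------------------
  p <- matrix(NA_real_, n, 2)
  pos <- if (is_epm) c(0, -(epm_half_extent(geometry) - 4)) else
    c(0.1 * geometry$arena_length, geometry$arena_width / 2)
  target <- sample_waypoint(geometry)
  dwell_tgt <- NULL
  dwell_until <- 0L
  dip_nose <- rep(0, n)             # lateral nose excursion, cm (EPM dips)
  script <- NULL
  script_i <- 0L
  next_ev <- if (n_ev > 0) 1L else 0L

  step_to <- function(pos, tgt, step_len) {
    if (is_epm) return(epm_route_step(pos, tgt, step_len))
    d <- tgt - pos
    len <- sqrt(sum(d^2))
    if (len <= step_len) tgt else pos + d / len * step_len
  }
  dist_to <- function(pos, tgt) {
    if (is_epm) epm_skeleton_dist(pos, tgt) else sqrt(sum((pos - tgt)^2))
  }
  # slow wander point near a waypoint; keeps background speed ~1 cm/s so the
  # mouse lingers without ever sitting below the freeze threshold
  dwell_point <- function(tgt) {
    if (is_epm) {
      len <- sqrt(sum(tgt^2))
      if (len < 1) {
        out <- c(0, 0)
        out[sample.int(2L, 1)] <- sample(c(-1, 1), 1) * stats::runif(1, 1, 3)
        return(out)
      }
      return(tgt - tgt / len * stats::runif(1, 1, 3))
    }
    repeat {
      cand <- tgt + stats::runif(2, -1, 1) * stats::runif(1, 1, 3)
      if (cand[1] > 1 && cand[2] > 1 && cand[1] < geometry$arena_length - 1 &&
          cand[2] < geometry$arena_width - 1) return(cand)
    }
  }

  make_script <- function(lab, pos) {
    if (lab == "freeze") {
      if (is_epm) {
        tgt <- if (sqrt(sum(pos^2)) < 4) c(0, epm_half_extent(geometry) - 3) else c(0, 0)
        list(label = lab, speed = freeze_speed_profile(travel, 30), target = tgt)
      } else {
        ctr <- c(geometry$arena_length * 0.35, geometry$arena_width / 2)
        d <- ctr - pos
        list(label = lab, speed = freeze_speed_profile(travel, 30),
             dir = d / max(sqrt(sum(d^2)), 1e-9))
      }
    } else if (lab == "head_dip") {
      nf <- 21L
      ny <- c(seq(0, 5, length.out = 4)[-1], rep(5, nf - 6),
              seq(5, 0, length.out = 4)[-4])
      list(label = lab, speed = rep(0.5, nf), dir = c(sign(pos[1]), 0),
           nose_y = ny)
    } else {                        # approach / escape
      u <- home - pos
      u <- u / max(sqrt(sum(u^2)), 1e-9)
      if (lab == "escape") u <- -u
      list(label = lab, speed = dash_speed_profile(travel, 30), dir = u)
    }
  }

  for (t in seq_len(n)) {
    if (is.null(script) && next_ev > 0L && next_ev <= n_ev && t >= slots[next_ev]) {
      script <- make_script(ev_labels[next_ev], pos)
      script_i <- 0L
      next_ev <- next_ev + 1L
      dwell_tgt <- NULL
    }
    if (!is.null(script)) {
      script_i <- script_i + 1L
      sp <- script$speed[script_i]
      if (script$label == "head_dip") {
        dip_nose[t] <- script$nose_y[script_i]
        pos <- pos + script$dir * sp * dt
      } else if (is_epm) {
        pos <- epm_route_step(pos, script$target, sp * dt)
      } else {
        pos <- pos + script$dir * sp * dt
      }
      if (script_i >= length(script$speed)) script <- NULL
      p[t, ] <- pos
      next
    }
    steer <- next_ev > 0L && next_ev <= n_ev &&
      !is.null(ev_start[[next_ev]]) && t >= slots[next_ev] - lead_s * fps
    if (steer) {
      tgt <- ev_start[[next_ev]]
      d <- dist_to(pos, tgt)
      if (d > 0.5) {
        rem <- max(slots[next_ev] - t, 1L)
        cap <- if (is_epm) 8 else 2.8
        sp <- min(cap, max(travel, d / (rem * dt) * 1.05))
        pos <- step_to(pos, tgt, sp * dt)
        dwell_tgt <- NULL
      } else {
        # arrived early: wander near the start point at ~1 cm/s, never
        # dropping below the freeze threshold for more than a frame
        if (is.null(dwell_tgt) || dist_to(pos, dwell_tgt) < 0.05)
          dwell_tgt <- tgt - tgt / max(sqrt(sum(tgt^2)), 1e-9) * stats::runif(1, 1, 3)
        pos <- step_to(pos, dwell_tgt, 1.0 * dt)
      }
    } else if (dwell_until >= t) {       # linger at the reached waypoint
      if (is.null(dwell_tgt) || dist_to(pos, dwell_tgt) < 0.05)
        dwell_tgt <- dwell_point(target)
      pos <- step_to(pos, dwell_tgt, 1.0 * dt)
      if (dwell_until == t) { target <- sample_waypoint(geometry); dwell_tgt <- NULL }
    } else {
      if (dist_to(pos, target) < 0.75) {
        dwell_until <- t + round(stats::runif(1, 3, 8) * fps)
        dwell_tgt <- NULL
      }
      pos <- step_to(pos, target, travel * dt)
    }
    p[t, ] <- pos
  }

  # ---- rat / toy trajectory ----------------------------------------------
  rat <- NULL
  rat_bursts <- NULL
  if (!is_epm) {
    rat <- matrix(rep(home, each = n), n, 2)
    if (kind == "RAT") {
      # slow circling around the tether point with gently varying speed
      # (max 0.3 cm/s). Planted bursts are monotone-decreasing from their
      # peak and together occupy > 0.5% of frames, so the 99.5th speed
      # percentile always falls inside the burst speed range: the frames
      # above it form a prefix of each burst and onsets stay exact.
      r0 <- 2
      spd_bg <- 0.2 + 0.1 * sin(2 * pi * seq_len(n) / (60 * fps) +
                                  stats::runif(1, 0, 2 * pi))
      ang <- cumsum(spd_bg / r0 * dt) + stats::runif(1, 0, 2 * pi)
      rat <- cbind(home[1] + r0 * cos(ang), home[2] + r0 * sin(ang))
      nb <- config$n_rat_movement
      if (nb > 0) {
        bs <- round(seq(0.15, 0.85, length.out = nb) * n) +
          round(stats::runif(nb, -0.03, 0.03) * n)
        nf_burst <- max(40L, ceiling(0.0055 * n / nb) + 5L)
        sp_prof <- seq(15, 2, length.out = nf_burst)
        rat_bursts <- data.frame(onset_frame = bs, angle = NA_real_,
                                 n_frames = nf_burst)
        for (b in seq_len(nb)) {
          t0 <- bs[b]
          aim <- c(stats::runif(1, 0.4, 0.6) * geometry$arena_length,
                   stats::runif(1, 8, geometry$arena_width - 8))
          u <- aim - rat[t0 - 1L, ]
          u <- u / sqrt(sum(u^2))
          to_mouse <- p[t0, ] - rat[t0 - 1L, ]
          rat_bursts$angle[b] <- ((atan2(u[2], u[1]) -
                                     atan2(to_mouse[2], to_mouse[1])) * 180 / pi) %% 360
          pos_r <- rat[t0 - 1L, ]
          for (k in seq_along(sp_prof)) {
            pos_r <- pos_r + u * sp_prof[k] * dt
            rat[t0 + k - 1L, ] <- pos_r
          }
          # walk back to the circling radius below background speed
          kk <- t0 + length(sp_prof)
          step <- 0.15 * dt
          while (kk <= n) {
            u <- pos_r - home
            len <- sqrt(sum(u^2))
            if (abs(len - r0) < step) {
              pos_r <- home + u / len * r0
              rat[kk, ] <- pos_r
              kk <- kk + 1L
              break
            }
            pos_r <- pos_r + u / len * sign(r0 - len) * step
            rat[kk, ] <- pos_r
            kk <- kk + 1L
          }
          if (kk <= n) {
            ang2 <- atan2(rat[kk - 1L, 2] - home[2], rat[kk - 1L, 1] - home[1])
            ang_rest <- ang2 + cumsum(spd_bg[kk:n] / r0 * dt)
            rat[kk:n, ] <- cbind(home[1] + r0 * cos(ang_rest),
                                 home[2] + r0 * sin(ang_rest))
          }
        }
      }
    }
  }

  # ---- keypoints from centroid + heading ---------------------------------
  v <- rbind(p[2, ] - p[1, ], diff(p))
  hd <- matrix(0, n, 2)
  last <- c(0, 1)
  for (t in seq_len(n)) {
    sp <- sqrt(sum(v[t, ]^2))
    if (sp > 1e-9) last <- v[t, ] / sp
    hd[t, ] <- last
  }
  # keypoint offsets sum to zero so the 4-keypoint centroid equals the true
  # body center regardless of heading (turning in place is not locomotion)
  perp <- cbind(-hd[, 2], hd[, 1])
  nose <- p + 1.0 * hd + dip_nose * perp
  tailbase <- p - 2.0 * hd
  ear_l <- p + 0.5 * hd + 1.0 * perp
  ear_r <- p + 0.5 * hd - 1.0 * perp
  if (config$pose_jitter_cm > 0) {
    jit <- function(m) m + matrix(stats::rnorm(2 * n, 0, config$pose_jitter_cm), n, 2)
    nose <- jit(nose); tailbase <- jit(tailbase); ear_l <- jit(ear_l); ear_r <- jit(ear_r)
  }
  dat <- data.frame(nose_x = nose[, 1], nose_y = nose[, 2],
                    ear_l_x = ear_l[, 1], ear_l_y = ear_l[, 2],
                    ear_r_x = ear_r[, 1], ear_r_y = ear_r[, 2],
                    tailbase_x = tailbase[, 1], tailbase_y = tailbase[, 2],
                    centroid_x = p[, 1], centroid_y = p[, 2])
  if (!is_epm) { dat$rat_x <- rat[, 1]; dat$rat_y <- rat[, 2] }
  pose <- pose_track(dat, fps = fps, geometry = geometry)

  # ---- ground truth -------------------------------------------------------
  raw_speed <- c(NA, sqrt(rowSums(diff(p)^2)) * fps)
  raw_speed[1] <- raw_speed[2]
  ev <- data.frame(label = character(), onset = numeric(), offset = numeric(),
                   angle = numeric())
  add_runs <- function(ev, flag, label, min_dur = 0.33) {
    r <- true_runs(flag)
    if (nrow(r)) r <- r[(r$end - r$start + 1L) / fps >= min_dur - 1e-9, , drop = FALSE]
    if (!nrow(r)) return(ev)
    rbind(ev, data.frame(label = label, onset = (r$start - 1L) / fps,
                         offset = r$end / fps, angle = NA_real_))
  }
  ev <- add_runs(ev, raw_speed < 0.25, "freeze")
  if (is_epm) {
    in_open <- abs(p[, 1]) > geometry$arm_width / 2 &
      abs(p[, 2]) <= geometry$arm_width / 2
    ev <- add_runs(ev, abs(dip_nose) > geometry$arm_width / 2 & in_open,
                   "head_dip", min_dur = 0.2)
  } else {
    d_rat <- sqrt(rowSums((p - rat)^2))
    # direction over a 0.33 s window (single-frame flips are not direction
    # changes; mirrors the direction-binarization rule downstream)
    idx <- seq_len(n)
    toward <- (d_rat[pmin(n, idx + 5L)] - d_rat[pmax(1L, idx - 5L)]) < 0
    ev <- add_runs(ev, raw_speed > 3 & toward, "approach")
    ev <- add_runs(ev, raw_speed > 3 & !toward, "escape")
    if (!is.null(rat_bursts) && nrow(rat_bursts)) {
      ev <- rbind(ev, data.frame(label = "rat_movement",
                                 onset = (rat_bursts$onset_frame - 1L) / fps,
                                 offset = (rat_bursts$onset_frame - 1L +
                                             rat_bursts$n_frames) / fps,
                                 angle = rat_bursts$angle))
    }
  }
  ev <- ev[order(ev$onset), ]
  truth_events <- behavior_intervals(ev$label, ev$onset, ev$offset,
                                     meta = data.frame(angle = ev$angle))

  # zone and state sequences
  if (is_epm) {
    w2 <- geometry$arm_width / 2
    zone <- ifelse(abs(p[, 1]) > w2 & abs(p[, 2]) <= w2,
                   ifelse(p[, 1] > 0, "open1", "open2"),
                   ifelse(abs(p[, 2]) > w2 & abs(p[, 1]) <= w2,
                          ifelse(p[, 2] > 0, "closed1", "closed2"), "center"))
    state <- ifelse(zone %in% c("open1", "open2"), "approach",
                    ifelse(zone %in% c("closed1", "closed2"), "avoid", "neutral"))
  } else {
    d_rat <- sqrt(rowSums((p - rat)^2))
    zone <- ifelse(p[, 1] <= geometry$safe_zone_fraction * geometry$arena_length,
                   "safe", ifelse(d_rat <= geometry$threat_radius_cm,
                                  "threatening", "middle"))
    state <- ifelse(zone == "safe", "avoid",
                    ifelse(zone == "threatening", "approach", "neutral"))
  }
  frz <- interval_indicator(truth_events, n, fps, "freeze")
  state[frz] <- "avoid"
  if (kind == "TOY") state <- rep("neutral", n)   # no threat modulation

  truth <- structure(list(cell_category = planted_categories(config),
                          state_sequence = state, zone_sequence = zone,
                          planted_event_table = truth_events,
                          fps = fps, n_frames = n,
                          session_length = config$session_length,
                          assay_kind = kind, seed = config$seed),
                     class = "ground_truth")
  list(pose = pose, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s session, %d frames, %d planted events, %d cells (%s)\n",
              x$assay_kind, x$n_frames, nrow(x$planted_event_table),
              length(x$cell_category),
              paste(names(table(x$cell_category)), table(x$cell_category),
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' Simulate population calcium activity
#'
#' Each cell's instantaneous rate is baseline + tuning x (indicator of its
#' preferred state): open-category cells respond during open-arm (EPM) /
#' approach-state (rat) frames, closed-category cells during closed-arm /
#' avoid-state frames, neither cells carry no tuning. Rates are convolved
#' with a single-exponential calcium kernel and Gaussian noise is added at
#' the configured SNR (tuning amplitude over noise SD). With
#' `artifact_amplitude > 0` a slow multiplicative bleaching ramp shared by
#' all cells is injected before any z-scoring. In the toy-rat condition no
#' cell is tuned.
#'
#' @param truth a `ground_truth` object from [simulate_behavior_session()].
#' @param config the matching [simulation_config()].
#' @return A [trace_matrix()] at `config$neural_hz`.
#' @export
simulate_population_activity <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"))
  if (config$snr <= 0) stop("snr must be > 0")
  with_seed(config$seed + 7919L, {
    ratio <- round(config$behavior_fps / config$neural_hz)
    n_t <- truth$n_frames %/% ratio
    blk <- function(x) colMeans(matrix(as.numeric(x[seq_len(n_t * ratio)]),
                                       nrow = ratio))
    if (truth$assay_kind == "EPM") {
      ind_open <- blk(truth$zone_sequence %in% c("open1", "open2"))
      ind_closed <- blk(truth$zone_sequence %in% c("closed1", "closed2"))
    } else {
      ind_open <- blk(truth$state_sequence == "approach")
      ind_closed <- blk(truth$state_sequence == "avoid")
    }
    if (truth$assay_kind == "TOY") ind_open <- ind_closed <- rep(0, n_t)
    dt <- 1 / config$neural_hz
    a <- exp(-dt / config$calcium_decay_tau)
    kern <- function(x) as.numeric(stats::filter(x, a, method = "recursive")) * (1 - a)
    drive <- rbind(open = kern(ind_open), closed = kern(ind_closed),
                   neither = rep(0, n_t))
    cat_idx <- match(truth$cell_category, rownames(drive))
    clean <- config$baseline_rate +
      config$tuning_strength * drive[cat_idx, , drop = FALSE]
    noise_sd <- config$tuning_strength / config$snr
    vals <- clean + matrix(stats::rnorm(length(clean), 0, noise_sd),
                           nrow = nrow(clean))
    if (config$artifact_amplitude > 0) {
      # photobleaching decays the baseline fluorescence over the whole
      # session, a slow exponential shared across all cells (transients
      # ride on top); power concentrates well below 0.01 Hz
      tgrid <- seq_len(n_t) * dt
      ramp <- config$artifact_amplitude * exp(-tgrid / config$session_length)
      vals <- sweep(vals, 2, ramp, `+`)
    }
    trace_matrix(vals, fs = config$neural_hz,
                 cell_ids = paste0("cell_", seq_len(config$n_cells)))
  })
}

#' Simulate a full session (behavior + activity)
#'
#' @inheritParams simulate_behavior_session
#' @return list with `pose`, `truth`, `traces`, `geometry`, `config`.
#' @export
simulate_session <- function(geometry, config) {
  beh <- simulate_behavior_session(geometry, config)
  traces <- simulate_population_activity(beh$truth, config)
  list(pose = beh$pose, truth = beh$truth, traces = traces,
       geometry = geometry, config = config)
}

#' Co-registration map between two synthetic sessions
#'
#' The first `round(coregistration_frac * n_cells)` cells are shared across
#' assays (identity pairing); with fraction 1 the map is the identity.
#'
#' @param config a [simulation_config()].
#' @return A [coregistration_map()].
#' @export
synthetic_coregistration <- function(config) {
  m <- round(config$coregistration_frac * config$n_cells)
  ids <- paste0("cell_", seq_len(m))
  coregistration_map(ids, ids)
}
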