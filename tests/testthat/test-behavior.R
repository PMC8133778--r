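# Constructed pose tracks for rule-level checks ---------------------------

make_pose <- function(cx, cy, geometry, rat = NULL, nose_dy = 0, fps = 30) {
  n <- length(cx)
  d <- data.frame(nose_x = cx + 1, nose_y = cy + nose_dy,
                  ear_l_x = cx + 0.5, ear_l_y = cy + 1,
                  ear_r_x = cx + 0.5, ear_r_y = cy - 1,
                  tailbase_x = cx - 2, tailbase_y = cy)
  if (!is.null(rat)) { d$rat_x <- rat[, 1]; d$rat_y <- rat[, 2] }
  pose_track(d, fps = fps, geometry = geometry)
}

rat_geom <- assay_geometry("RAT")
epm_geom <- assay_geometry("EPM")

test_that("kinematics: stationary, straight-line and circular tracks", {
  n <- 100
  still <- make_pose(rep(5, n), rep(5, n), rat_geom,
                     rat = cbind(rep(60, n), rep(13, n)))
  k <- compute_kinematics(still)
  expect_true(all(k$speed == 0) && all(k$speed_head == 0))

  line <- make_pose(seq(1, 1 + (n - 1) * 1, by = 1), rep(5, n),
                    assay_geometry("RAT", arena_length = 200),
                    rat = cbind(rep(150, n), rep(5, n)))
  k2 <- compute_kinematics(line)
  expect_equal(k2$speed, rep(30, n), tolerance = 1e-9)

  # circle around the rat: constant speed, zero radial velocity
  th <- seq(0, 4 * pi, length.out = 600)
  circ <- make_pose(35 + 10 * cos(th), 13 + 10 * sin(th), rat_geom,
                    rat = cbind(rep(35, 600), rep(13, 600)))
  k3 <- compute_kinematics(circ)
  expect_lt(diff(range(k3$speed[20:580])), 1e-6)
  expect_lt(max(abs(k3$radial_velocity)), 1e-8)
  expect_error(compute_kinematics(make_pose(1, 1, epm_geom)), "2 frames")
})

test_that("freeze rule: threshold, duration and head-tail conjunction", {
  mk_kin <- function(head_speed, tail_speed, fps = 30) {
    n <- length(head_speed)
    structure(data.frame(speed_head = head_speed, speed_tail = tail_speed,
                         speed = (head_speed + tail_speed) / 2),
              fps = fps, assay = "EPM", class = c("kinematic_series", "data.frame"))
  }
  slow6 <- rep(0.2, 6)                       # 0.2 s: too short
  base <- rep(2, 30)
  expect_equal(nrow(detect_freeze(mk_kin(c(base, slow6, base), c(base, slow6, base)))), 0)
  slow12 <- rep(0.2, 12)                     # 0.4 s: long enough
  expect_equal(nrow(detect_freeze(mk_kin(c(base, slow12, base), c(base, slow12, base)))), 1)
  # head slow but tailbase above threshold: no freeze
  expect_equal(nrow(detect_freeze(mk_kin(c(base, slow12, base),
                                         rep(0.3, 72)))), 0)
})

test_that("approach/escape rule: 3 cm/s threshold, direction, assay guard", {
  n <- 120
  # monotone run toward the rat at 5 cm/s
  toward <- make_pose(seq(20, 20 + (n - 1) * 5 / 30, by = 5 / 30), rep(13, n),
                      rat_geom, rat = cbind(rep(65, n), rep(13, n)))
  iv <- detect_approach_escape(compute_kinematics(toward))
  expect_equal(unique(iv$label), "approach")
  expect_equal(nrow(iv), 1)

  slow <- make_pose(seq(20, 20 + (n - 1) * 2 / 30, by = 2 / 30), rep(13, n),
                    rat_geom, rat = cbind(rep(65, n), rep(13, n)))
  expect_equal(nrow(detect_approach_escape(compute_kinematics(slow))), 0)

  away <- make_pose(seq(60, 60 - (n - 1) * 5 / 30, by = -5 / 30), rep(13, n),
                    rat_geom, rat = cbind(rep(65, n), rep(13, n)))
  iv3 <- detect_approach_escape(compute_kinematics(away))
  expect_equal(unique(iv3$label), "escape")

  epm_pose <- make_pose(rep(0, 10), seq(0, 9, 1), epm_geom)
  expect_error(detect_approach_escape(compute_kinematics(epm_pose)),
               "rat-arena")
})

test_that("rat movements: percentile threshold, 5.33 s merge, direction angle", {
  n <- 3000
  # lunge: decaying-speed dash along dx that persists (no teleport back)
  lunge <- function(rx, start, dx = 1) {
    steps <- dx * seq(0.5, 0.05, length.out = 10)   # 15 -> 1.5 cm/s
    rx[start:n] <- rx[start - 1] + c(cumsum(steps),
                                     rep(sum(steps), n - start - 9))
    rx
  }
  rx <- rep(55, n)
  rx <- lunge(rx, 1000); rx <- lunge(rx, 1090)      # 3 s apart
  pose <- make_pose(rep(20, n), rep(13, n), rat_geom,
                    rat = cbind(rx, rep(13, n)))
  iv <- detect_rat_movements(compute_kinematics(pose))
  expect_equal(nrow(iv), 1)                 # second burst inside refractory
  expect_equal(iv$onset, 999 / 30, tolerance = 1e-9)

  # stationary rat: no events
  still <- make_pose(rep(20, n), rep(13, n), rat_geom,
                     rat = cbind(rep(60, n), rep(13, n)))
  expect_equal(nrow(detect_rat_movements(compute_kinematics(still))), 0)

  # burst straight at the mouse: angle ~ 0
  rx2 <- lunge(rep(60, n), 1500, dx = -1)   # toward mouse at x = 20
  pose2 <- make_pose(rep(20, n), rep(13, n), rat_geom,
                     rat = cbind(rx2, rep(13, n)))
  iv2 <- detect_rat_movements(compute_kinematics(pose2))
  ang <- iv2$angle[which.min(abs(iv2$onset - 1499 / 30))]
  expect_lt(min(ang, 360 - ang), 5)
})

test_that("head dips need nose-out geometry AND open-arm occupancy", {
  n <- 90
  # nose inside the arm the whole time
  inside <- make_pose(rep(15, n), rep(0, n), epm_geom)
  z <- assign_zones(inside)
  expect_equal(nrow(detect_head_dips(inside, z)), 0)
  # nose beyond the lateral edge for 0.5 s while in an open arm
  dip <- make_pose(rep(15, n), rep(0, n), epm_geom,
                   nose_dy = c(rep(0, 30), rep(5, 15), rep(0, 45)))
  iv <- detect_head_dips(dip, assign_zones(dip))
  expect_equal(nrow(iv), 1)
  # same nose geometry but the mouse is in a closed arm: not a dip
  closed <- make_pose(rep(0, n), rep(15, n), epm_geom,
                      nose_dy = c(rep(0, 30), rep(5, 15), rep(0, 45)))
  expect_equal(nrow(detect_head_dips(closed, assign_zones(closed))), 0)
})

test_that("zones: safe by x, threatening inclusive at 14 cm, EPM center", {
  p1 <- make_pose(0.1 * 70, 13, rat_geom, rat = cbind(60, 13))
  p1$data <- rbind(p1$data, p1$data); p1$n_frames <- 2
  expect_equal(assign_zones(p1)[1], "safe")
  # distance exactly 14 cm: threatening (inclusive)
  p2 <- make_pose(c(46, 46), rep(13, 2), rat_geom, rat = cbind(rep(60, 2), rep(13, 2)))
  expect_equal(assign_zones(p2)[1], "threatening")
  p3 <- make_pose(c(45.9, 45.9), rep(13, 2), rat_geom, rat = cbind(rep(60, 2), rep(13, 2)))
  expect_equal(assign_zones(p3)[1], "middle")
  ctr <- make_pose(c(0, 0), c(0, 0), epm_geom)
  expect_equal(assign_zones(ctr)[1], "center")
  out <- make_pose(c(200, 200), c(0, 0), epm_geom)
  expect_error(assign_zones(out), "outside")
})

test_that("location index: open end 1, center 0, closed end -1, arithmetic", {
  he <- 33.5
  pose <- make_pose(c(he, 0, 0, 0.5 * he), c(0, 0, -he, 0.3 * he), epm_geom)
  li <- epm_location_index(pose)
  expect_equal(li$location_index, c(1, 0, -1, 0.2), tolerance = 1e-9)
})

test_that("avoidance/approach score: freeze floor, rat adjacency, head dips", {
  n <- 60
  # toward the rat, ending adjacent to it
  cx <- seq(40, 70, length.out = n)
  pose <- make_pose(cx, rep(13, n), rat_geom,
                    rat = cbind(rep(70, n), rep(13, n)))
  sc <- avoidance_approach_score(pose, behavior_intervals(), rat_geom)
  expect_equal(sc$score[n], 1, tolerance = 1e-9)        # adjacent, toward
  expect_true(all(sc$direction == 1))

  # freeze frames are forced to -1 wherever the mouse is
  frz <- behavior_intervals("freeze", 0.5, 1.0)
  sc2 <- avoidance_approach_score(pose, frz, rat_geom)
  expect_true(all(sc2$score[16:30] == -1))

  # head dip over the end of an open arm: body center reaches the arm
  # extremity (distance-to-safety 0.9), nose over the end edge; the score
  # is 0.9 * 1.11 = 0.999, i.e. 1.00 at two decimals
  m <- 40
  cx <- seq(25, 33.5, length.out = m)
  pose3 <- pose_track(data.frame(nose_x = cx + 2, nose_y = 0,
                                 ear_l_x = cx + 0.5, ear_l_y = 1,
                                 ear_r_x = cx + 0.5, ear_r_y = -1,
                                 tailbase_x = cx - 3, tailbase_y = 0),
                      fps = 30, geometry = epm_geom)
  dips <- behavior_intervals("head_dip", 0, m / 30)
  sc3 <- avoidance_approach_score(pose3, dips, epm_geom)
  expect_equal(round(sc3$score[m], 2), 1)
  expect_equal(sc3$dist_safety[m], 0.9, tolerance = 1e-9)

  # score ranges hold on full synthetic sessions
  for (s in list(epm_session(), rat_session())) {
    pr <- processed_session(s)
    expect_true(all(pr$behavior$score >= -1 & pr$behavior$score <= 1))
  }
})

test_that("EPM mirror symmetry swaps arm labels, |index| unchanged", {
  s <- epm_session()
  pose <- s$pose
  li <- epm_location_index(pose)
  z <- assign_zones(pose)
  flip <- pose
  for (cc in grep("_x$", names(flip$data), value = TRUE))
    flip$data[[cc]] <- -flip$data[[cc]]
  li_f <- epm_location_index(flip)
  z_f <- assign_zones(flip)
  expect_equal(abs(li$location_index), abs(li_f$location_index), tolerance = 1e-12)
  expect_true(all(z_f[z == "open1"] == "open2"))
  expect_true(all(z_f[z == "center"] == "center"))
})

test_that("detectors are invariant to rigid arena translation", {
  s <- rat_session()
  kin <- compute_kinematics(s$pose)
  shift <- s$pose
  for (cc in grep("_x$", names(shift$data), value = TRUE))
    shift$data[[cc]] <- shift$data[[cc]] + 12.3
  for (cc in grep("_y$", names(shift$data), value = TRUE))
    shift$data[[cc]] <- shift$data[[cc]] + 4.56
  kin2 <- compute_kinematics(shift)
  expect_equal(detect_freeze(kin), detect_freeze(kin2))
  expect_equal(detect_approach_escape(kin), detect_approach_escape(kin2))
  expect_equal(detect_rat_movements(kin), detect_rat_movements(kin2))
})

test_that("planted events are recovered with <= 1 frame onset error and F1 > 0.9", {
  fps <- 30
  score_f1 <- function(truth, det, lab) {
    tt <- truth[truth$label == lab, ]; dd <- det[det$label == lab, ]
    tp <- sum(vapply(tt$onset, function(o)
      any(abs(dd$onset - o) * fps <= 1.5), logical(1)))
    2 * tp / (nrow(tt) + nrow(dd))
  }
  s <- epm_session()
  kin <- compute_kinematics(s$pose)
  det <- combine_intervals(detect_freeze(kin),
                           detect_head_dips(s$pose, assign_zones(s$pose)))
  for (lab in c("freeze", "head_dip")) {
    expect_gt(score_f1(s$truth$planted_event_table, det, lab), 0.9)
    expect_lte(max(onset_errors(s$truth$planted_event_table, det, lab)), 1.5)
  }
  sr <- rat_session()
  kr <- compute_kinematics(sr$pose)
  detr <- combine_intervals(detect_freeze(kr), detect_approach_escape(kr),
                            detect_rat_movements(kr))
  for (lab in c("freeze", "approach", "escape", "rat_movement")) {
    expect_gt(score_f1(sr$truth$planted_event_table, detr, lab), 0.9)
    expect_lte(max(onset_errors(sr$truth$planted_event_table, detr, lab)), 1.5)
  }
})
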