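zones_of <- function(labels, each) rep(labels, each = each)

tm_from <- function(mat) trace_matrix(mat, fs = 7.5, is_zscored = TRUE)

test_that("preference score equals the brute-force all-pairs AUC", {
  brute_auc <- function(pos, neg) {
    wins <- 0
    for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
    wins / (length(pos) * length(neg))
  }
  set.seed(21)
  for (i in 1:20) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    pos <- round(rnorm(n1), 1)             # rounding forces ties
    neg <- round(rnorm(n2, 0.3), 1)
    zones <- c(rep("open1", n1), rep("closed1", n2))
    tm <- tm_from(matrix(c(pos, neg), 1))
    got <- open_arm_preference_score(tm, zones)
    expect_equal(got$auc, brute_auc(pos, neg), tolerance = 1e-12)
    expect_equal(got$preference_score, 2 * brute_auc(pos, neg) - 1,
                 tolerance = 1e-12)
  }
})

test_that("preference score boundary values", {
  zones <- c(rep("open1", 3), rep("closed1", 3))
  # strict separation: +1
  strict <- open_arm_preference_score(tm_from(matrix(c(2, 3, 4, 0, 0.5, 1), 1)), zones)
  expect_equal(strict$preference_score, 1)
  # identical distributions: 0
  same <- open_arm_preference_score(tm_from(matrix(c(1, 2, 3, 1, 2, 3), 1)), zones)
  expect_equal(same$preference_score, 0)
  # open {1,3} vs closed {2}: AUC 0.5 by pair counting
  z2 <- c("open1", "open2", "closed1")
  mid <- open_arm_preference_score(tm_from(matrix(c(1, 3, 2), 1)), z2)
  expect_equal(mid$preference_score, 0)
  expect_error(open_arm_preference_score(tm_from(matrix(1:3, 1)),
                                         rep("open1", 3)),
               "never visited")
})

test_that("label-swap antisymmetry negates the preference score", {
  set.seed(8)
  zones <- sample(c("open1", "open2", "closed1", "closed2", "center"),
                  200, replace = TRUE)
  tm <- tm_from(matrix(rnorm(5 * 200), 5))
  swap <- function(z) c(open1 = "closed1", open2 = "closed2",
                        closed1 = "open1", closed2 = "open2",
                        center = "center")[z]
  a <- open_arm_preference_score(tm, zones)$preference_score
  b <- open_arm_preference_score(tm, swap(zones))$preference_score
  expect_equal(a, -b, tolerance = 1e-12)
})

test_that("EPM score formula: boundary, hand-computed and degenerate cases", {
  expect_equal(epm_score(1, 1, 0, 0), 1)            # B = 0
  expect_equal(epm_score(1, 0, 1, 0), -1 / 3)       # A = 0.5, B = 1
  expect_equal(epm_score(2, 2, 2, 2), 0)            # defined as 0
  set.seed(3)
  f <- matrix(rnorm(40), 10)
  sc <- epm_score(f[, 1], f[, 2], f[, 3], f[, 4])
  expect_true(all(sc >= -1 & sc <= 1))
})

test_that("categorization needs both open arms and beats pooled closed", {
  set.seed(5)
  n_per <- 120
  zones <- zones_of(c("open1", "open2", "closed1", "closed2"), n_per)
  base <- function() rnorm(4 * n_per, 0, 0.3)
  both <- base(); both[zones %in% c("open1", "open2")] <- rnorm(2 * n_per, 1, 0.3)
  one <- base(); one[zones == "open1"] <- rnorm(n_per, 1, 0.3)
  flat <- rep(0.5, 4 * n_per)
  closedc <- base(); closedc[zones %in% c("closed1", "closed2")] <- rnorm(2 * n_per, 1, 0.3)
  tm <- tm_from(rbind(both, one, flat, closedc))
  lab <- categorize_arm_cells(tm, zones)
  expect_equal(lab$category, c("open", "neither", "neither", "closed"))
})

test_that("40/60 split withholds the later samples after a 10 s gap", {
  s <- epm_session()
  pr <- processed_session(s, key = "epm_proc")
  # an arm may go unvisited within the first 40%; only the index
  # arithmetic is under test here
  lab <- suppressWarnings(
    categorize_arm_cells(pr$traces, pr$behavior$zone, split = "40/60"))
  wi <- attr(lab, "withheld_idx")
  n <- ncol(pr$traces$values)
  expect_equal(min(wi), floor(0.4 * n) + ceiling(10 * 7.5) + 1)
  expect_equal(max(wi), n)
})

test_that("planted categories are recovered at snr 5 (balanced accuracy > 0.9)", {
  s <- epm_session()
  pr <- processed_session(s, key = "epm_proc")
  lab <- categorize_arm_cells(pr$traces, pr$behavior$zone)
  tru <- truth_categories(s, lab$cell_id)
  ba <- mean(vapply(c("open", "closed", "neither"), function(cc)
    mean(lab$category[tru == cc] == cc), numeric(1)))
  expect_gt(ba, 0.9)
})

test_that("at vanishing snr the open/closed fraction matches the test's
           false-positive rate", {
  set.seed(77)
  zones <- sample(c("open1", "open2", "closed1", "closed2"), 600,
                  replace = TRUE)
  noise <- tm_from(matrix(rnorm(200 * 600), 200))
  lab <- categorize_arm_cells(noise, zones)
  frac <- mean(lab$category != "neither")
  expect_lt(frac, 0.1)          # each one-sided pair is bounded by alpha
  expect_gt(frac, 0)            # but false positives do occur
})

test_that("peri-event traces, delta windows, boundary and exclusion rules", {
  fs <- 7.5
  n <- 600
  x <- rep(0, n)
  on_s <- c(20, 40, 60)
  iv <- behavior_intervals(rep("freeze", 3), on_s, on_s + 2)
  for (o in on_s) x[(floor(o * fs) + 1):n] <- x[(floor(o * fs) + 1):n] + 0
  # unit step at each onset (lasting beyond the post window)
  for (o in on_s) x[(floor(o * fs) + 1):(floor(o * fs) + 40)] <- 1
  tm <- tm_from(matrix(x, 1))
  pe <- peri_event_analysis(tm, iv, "freeze")
  expect_equal(pe$n_events, 3)
  expect_equal(unname(pe$delta), 1, tolerance = 1e-9)

  # event too close to the session start is dropped
  iv2 <- behavior_intervals(rep("freeze", 2), c(1, 40), c(2, 42))
  pe2 <- peri_event_analysis(tm, iv2, "freeze")
  expect_equal(pe2$n_events, 1)

  # a freeze 5 s after an escape is excluded under the 10 s rule
  iv3 <- combine_intervals(behavior_intervals("escape", 35, 36),
                           behavior_intervals("freeze", c(40, 70), c(41, 71)))
  pe3 <- peri_event_analysis(tm, iv3, "freeze", exclude_label = "escape")
  expect_equal(pe3$n_events, 1)
  expect_error(peri_event_analysis(tm, iv3, "approach"), "no 'approach'")

  # head-dip windows: pre [-5, -2.5]
  pe4 <- peri_event_analysis(tm, iv, "freeze", pre_window = c(-5, -2.5))
  expect_equal(unname(pe4$delta), 1, tolerance = 1e-9)
})

test_that("correlation table: exact, null and planted-structure cases", {
  set.seed(13)
  n <- 1000
  speed <- abs(rnorm(n))
  tm <- tm_from(rbind(speed, matrix(rnorm(20 * n), 20)))
  out <- activity_correlations(tm, covariates = data.frame(speed = speed))
  expect_equal(out$per_cell$r_speed[1], 1, tolerance = 1e-12)
  expect_gt(mean(abs(out$per_cell$r_speed[-1]) < 0.1), 0.9)

  flat <- activity_correlations(tm, covariates = data.frame(k = rep(1, n)))
  expect_true(all(is.na(flat$per_cell$r_k)))

  # anti-symmetric planted tuning: negative open-vs-closed correlation
  s <- epm_session()
  pr <- processed_session(s, key = "epm_proc")
  ac <- activity_correlations(pr$traces, zones = pr$behavior$zone)
  expect_lt(ac$across_cells$r_open_closed, 0)
  expect_gt(ac$across_cells$r_open1_open2, 0)
})

test_that("spatial maps are occupancy-normalized and masked", {
  set.seed(2)
  n <- 400
  xy <- data.frame(x = runif(n, 0, 20), y = runif(n, 0, 10))
  tm <- tm_from(matrix(rep(2.5, n), 1))
  sm <- spatial_activity_map(tm, xy, bin_cm = 2, min_occupancy = 1)
  vals <- sm$maps[, , 1]
  expect_true(all(abs(vals[sm$occupancy > 0] - 2.5) < 1e-12))
  expect_true(all(is.na(vals[sm$occupancy == 0])))

  # a cell tuned near the rat peaks inside the threatening zone
  sr <- rat_session()
  pr <- processed_session(sr, key = "rat_proc")
  al <- align_timebases(zscore_traces(sr$traces),
                        data.frame(x = sr$pose$data$centroid_x,
                                   y = sr$pose$data$centroid_y), fps = 30)
  cats <- truth_categories(sr, al$traces$cell_ids)
  open_cell <- which(cats == "open")[1]    # approach/threat-tuned
  sm2 <- spatial_activity_map(al$traces, al$behavior, bin_cm = 5,
                              min_occupancy = 5)
  mp <- sm2$maps[, , open_cell]
  pk <- which(mp == max(mp, na.rm = TRUE), arr.ind = TRUE)[1, ]
  pk_x <- sm2$x_breaks[pk[1]] + 2.5
  expect_gt(pk_x, 0.6 * 70)                # near the rat wall
})
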