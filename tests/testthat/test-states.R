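test_that("AIC table follows RSS + 2MK and K=1 reduces to the grand mean", {
  set.seed(51)
  tm <- trace_matrix(matrix(rnorm(10 * 200), 10), fs = 7.5, is_zscored = TRUE)
  km <- fit_kmeans_with_aic(tm, k_range = 1:4, seed = 1)
  M <- 10
  expect_equal(km$aic_table$aic, km$aic_table$rss + 2 * M * km$aic_table$K,
               tolerance = 1e-12)
  km1 <- fit_kmeans_with_aic(tm, k_range = 1, seed = 1)
  expect_equal(as.numeric(km1$centroids), rowMeans(tm$values),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(fit_kmeans_with_aic(tm, k_range = 500), "timepoints")
})

test_that("AIC selects the planted K on 10-sigma-separated blobs", {
  set.seed(52)
  d <- 60; T_ <- 300; sd0 <- 0.5
  mu2 <- rep(10 * sd0 / sqrt(d), d)          # separation 10 sigma
  x <- rbind(matrix(rnorm(T_ / 2 * d, 0, sd0), ncol = d),
             sweep(matrix(rnorm(T_ / 2 * d, 0, sd0), ncol = d), 2, mu2, "+"))
  tm <- trace_matrix(t(x), fs = 7.5, is_zscored = TRUE)
  km <- fit_kmeans_with_aic(tm, k_range = 1:6, seed = 2)
  expect_equal(km$K, 2)
  # centroids match the planted means (RMS error per dimension)
  cen <- km$centroids[order(km$centroids[, 1]), ]
  rms <- sqrt(mean((cen - rbind(rep(0, d), mu2))^2))
  expect_lt(rms, 0.1)
  # assignment minimizes distance to own centroid
  d2 <- as.matrix(dist(rbind(km$centroids, x)))[1:2, -(1:2)]
  expect_equal(unname(apply(d2, 2, which.min)), unname(km$assignment))
})

test_that("k-means is invariant to timepoint order", {
  set.seed(53)
  tm <- trace_matrix(matrix(rnorm(6 * 240), 6), fs = 7.5, is_zscored = TRUE)
  km1 <- fit_kmeans_with_aic(tm, k_range = 2, seed = 4)
  perm <- sample(240)
  tm2 <- trace_matrix(tm$values[, perm], fs = 7.5, is_zscored = TRUE)
  km2 <- fit_kmeans_with_aic(tm2, k_range = 2, seed = 4)
  expect_equal(km1$rss, km2$rss, tolerance = 1e-8)
  expect_equal(sort(km1$centroids[, 1]), sort(km2$centroids[, 1]),
               tolerance = 1e-8)
})

test_that("cluster labeling: extremes, ties and degenerate cases", {
  model <- structure(list(K = 3, centroids = matrix(0, 3, 2),
                          assignment = rep(1:3, each = 10)),
                     class = "cluster_model")
  sc <- c(rep(-0.4, 10), rep(0.1, 10), rep(0.5, 10))
  m <- label_state_clusters(model, sc)
  expect_equal(m$avoidance_cluster, 1)
  expect_equal(m$approach_cluster, 3)
  # equal means: tie broken to the lower index, with a warning
  model2 <- structure(list(K = 2, centroids = matrix(0, 2, 2),
                           assignment = rep(1:2, each = 5)),
                      class = "cluster_model")
  expect_warning(m2 <- label_state_clusters(model2, rep(0.2, 10)), "tied")
  expect_equal(m2$avoidance_cluster, 1)
})

test_that("permutation null: exchangeability, coverage and planted effects", {
  set.seed(54)
  n <- 900
  model <- structure(list(K = 3, centroids = matrix(0, 3, 2),
                          assignment = sample(1:3, n, replace = TRUE)),
                     class = "cluster_model")
  # scores independent of clusters: observed inside the null band
  sc <- rnorm(n, 0, 0.3)
  m <- label_state_clusters(model, sc)
  nul <- cluster_permutation_null(m, sc, n_perm = 100, seed = 5)
  expect_false(nul$approach_significant && nul$avoidance_significant)
  # permuted mean-of-means stays near the overall mean
  expect_lt(abs(mean(c(nul$null_max, nul$null_min)) - mean(sc)), 0.05)
  expect_warning(cluster_permutation_null(m, sc, n_perm = 10, seed = 1),
                 "unstable")

  # perfectly cluster-aligned scores are always outside the null
  sc2 <- c(-0.8, 0, 0.8)[model$assignment] + rnorm(n, 0, 0.01)
  m2 <- label_state_clusters(model, sc2)
  nul2 <- cluster_permutation_null(m2, sc2, n_perm = 100, seed = 6)
  expect_true(nul2$approach_significant)
  expect_true(nul2$avoidance_significant)
})

test_that("planted avoid/approach coding is found and survives transfer", {
  # fast calcium kernel isolates cluster-state correspondence from the
  # boundary smearing a 2 s kernel introduces
  cfgf <- rat_config(seed = 55, calcium_decay_tau = 0.5)
  sf <- simulate_session(assay_geometry("RAT"), cfgf)
  pf <- processed_session(sf)
  ratio <- 4
  n_t <- ncol(pf$traces$values)
  st <- sf$truth$state_sequence[seq_len(n_t * ratio)]
  stn <- apply(matrix(st, nrow = ratio), 2,
               function(b) names(which.max(table(b))))
  km <- label_state_clusters(fit_kmeans_with_aic(pf$traces, k_range = 3,
                                                 seed = 2),
                             pf$behavior$score)
  jac <- function(a, b) sum(a & b) / sum(a | b)
  expect_gt(jac(km$assignment == km$approach_cluster, stn == "approach"), 0.8)
  expect_gt(jac(km$assignment == km$avoidance_cluster, stn == "avoid"), 0.8)
  nul <- cluster_permutation_null(km, pf$behavior$score, n_perm = 100, seed = 3)
  expect_true(nul$approach_significant)
  expect_true(nul$avoidance_significant)
})

test_that("toy-rat sessions show no avoidance/approach coding", {
  pt <- processed_session(toy_session(), key = "toy_proc")
  km <- label_state_clusters(fit_kmeans_with_aic(pt$traces, k_range = 3,
                                                 seed = 2),
                             pt$behavior$score)
  nul <- cluster_permutation_null(km, pt$behavior$score, n_perm = 100, seed = 3)
  expect_false(nul$approach_significant)
  expect_false(nul$avoidance_significant)
})

test_that("cross-assay transfer: identity case, brute-force oracle, controls", {
  sr <- rat_session()
  pr <- processed_session(sr, key = "rat_proc")
  coreg <- synthetic_coregistration(rat_config())
  idx <- match(coreg$cell_id_assay1, pr$traces$cell_ids)
  sub <- trace_matrix(pr$traces$values[idx, ], fs = 7.5,
                      cell_ids = pr$traces$cell_ids[idx], is_zscored = TRUE)
  km <- label_state_clusters(fit_kmeans_with_aic(sub, k_range = 3, seed = 2),
                             pr$behavior$score)

  # identity transfer reproduces the original assignment
  tr_id <- transfer_clusters_across_assays(km, sub, coreg, pr$behavior$score)
  expect_equal(unname(tr_id$assignment), unname(km$assignment))

  # nearest-centroid equals brute-force distance minimization
  x <- t(sub$values[, 1:500])
  brute <- apply(x, 1, function(p)
    which.min(colSums((t(km$centroids) - p)^2)))
  expect_equal(unname(tr_id$assignment[1:500]), unname(brute))

  # planted shared coding: approach > avoidance scores in the other assay
  pe <- processed_session(epm_session(), key = "epm_proc")
  tr <- transfer_clusters_across_assays(km, pe$traces, coreg,
                                        pe$behavior$score)
  planted_sep <- tr$approach_mean - tr$avoidance_mean
  expect_gt(planted_sep, 0)
  expect_lt(tr$p_ranksum, 0.05)

  # TOY-trained centroids transferred to the rat assay: separation collapses
  pt <- processed_session(toy_session(), key = "toy_proc")
  idxT <- match(coreg$cell_id_assay1, pt$traces$cell_ids)
  subT <- trace_matrix(pt$traces$values[idxT, ], fs = 7.5,
                       cell_ids = pt$traces$cell_ids[idxT], is_zscored = TRUE)
  kmT <- label_state_clusters(fit_kmeans_with_aic(subT, k_range = 3, seed = 2),
                              pt$behavior$score)
  trT <- transfer_clusters_across_assays(kmT, pr$traces, coreg,
                                         pr$behavior$score)
  control_sep <- abs(trT$approach_mean - trT$avoidance_mean)
  expect_gt(planted_sep, 2 * control_sep)

  expect_error(transfer_clusters_across_assays(km, sub,
                                               coregistration_map(character(), character()),
                                               pr$behavior$score),
               "empty")
})

test_that("Gaussian HMM: stochastic rows, planted 2-state recovery, EM ascent", {
  set.seed(57)
  T_ <- 800
  states <- numeric(T_); states[1] <- 1
  for (t in 2:T_) states[t] <- if (runif(1) < 0.95) states[t - 1] else 3 - states[t - 1]
  obs <- matrix(rnorm(T_ * 3, mean = 5 * (states - 1)), ncol = 3)
  tm <- trace_matrix(t(obs), fs = 7.5, is_zscored = TRUE)
  hm <- fit_hmm_states(tm, n_states = 2, seed = 3)
  expect_equal(unname(rowSums(hm$transmat)), c(1, 1), tolerance = 1e-9)
  acc <- max(mean(hm$assignment == states), mean(hm$assignment == 3 - states))
  expect_gt(acc, 0.9)
  expect_true(all(diff(hm$loglik_trace) > -1e-6))    # EM ascent
  expect_gte(hm$n_pcs, 1)

  # HMM states label and analyze exactly like k-means clusters
  sc <- c(-0.5, 0.5)[states] + rnorm(T_, 0, 0.05)
  hm2 <- label_state_clusters(hm, sc)
  expect_true(hm2$approach_cluster != hm2$avoidance_cluster)
  nul <- cluster_permutation_null(hm2, sc, n_perm = 50, seed = 4)
  expect_true(nul$approach_significant)
})
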