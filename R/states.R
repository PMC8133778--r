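# Unsupervised avoidance/approach state discovery: k-means with AIC model
# selection, score-based cluster labeling, permutation nulls, cross-assay
# centroid transfer, and a Gaussian-HMM alternative on PCA inputs.

#' k-Means clustering of neural timepoints with AIC model selection
#'
#' Timepoints (dimensions = cells) are clustered for each candidate K using
#' `n_init` seeded random initializations, keeping the solution with the
#' minimum within-cluster sum of squared Euclidean distances. Assuming
#' Gaussian clusters with identity covariance, AIC = RSS_min(K) + 2 M K
#' with M the number of cells; the selected K minimizes AIC.
#'
#' @param traces a z-scored [trace_matrix()].
#' @param k_range candidate cluster counts (default 1:10).
#' @param n_init random initializations per K.
#' @param seed base RNG seed (one derived seed per K and init).
#' @return list of class `cluster_model`: `K`, `centroids` (K x cells),
#'   `assignment`, `rss`, `aic_table`.
#' @export
fit_kmeans_with_aic <- function(traces, k_range = 1:10, n_init = 10, seed = 1) {
  stopifnot(inherits(traces, "trace_matrix"))
  x <- t(traces$values)
  if (max(k_range) > nrow(x)) stop("more clusters requested than timepoints")
  M <- ncol(x)
  fits <- list()
  aic_table <- data.frame(K = k_range, rss = NA_real_, aic = NA_real_)
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    best <- NULL
    for (init in seq_len(n_init)) {
      km <- with_seed(seed + 97L * K + init, tryCatch(
        stats::kmeans(x, centers = K, iter.max = 100),
        error = function(e) NULL))            # empty-cluster init: skip
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop("k-means failed for K = ", K)
    fits[[i]] <- best
    aic_table$rss[i] <- best$tot.withinss
    aic_table$aic[i] <- best$tot.withinss + 2 * M * K
  }
  sel <- which.min(aic_table$aic)
  best <- fits[[sel]]
  structure(list(K = k_range[sel], centroids = best$centers,
                 assignment = best$cluster, rss = aic_table$rss[sel],
                 aic_table = aic_table, cell_ids = traces$cell_ids),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K = %d (AIC-selected over %s), RSS %.1f\n",
              x$K, paste(range(x$aic_table$K), collapse = "-"), x$rss))
  if (!is.null(x$avoidance_cluster))
    cat(sprintf("  avoidance cluster %d (mean score %.3f), approach cluster %d (%.3f)\n",
                x$avoidance_cluster, x$cluster_score_means[x$avoidance_cluster],
                x$approach_cluster, x$cluster_score_means[x$approach_cluster]))
  invisible(x)
}

#' Label clusters by mean avoidance/approach score
#'
#' The avoidance cluster has the minimum mean score, the approach cluster
#' the maximum; ties break to the lower cluster index (with a warning).
#'
#' @param model a `cluster_model` (or the result of [fit_hmm_states()]).
#' @param scores per-timepoint avoidance/approach scores aligned to the
#'   model's assignment.
#' @return the model with `cluster_score_means`, `avoidance_cluster` and
#'   `approach_cluster` fields filled in.
#' @export
label_state_clusters <- function(model, scores) {
  stopifnot(length(scores) == length(model$assignment))
  ids <- seq_len(max(model$assignment))
  mu <- vapply(ids, function(k) mean(scores[model$assignment == k]), numeric(1))
  if (anyNA(mu)) stop("empty cluster encountered; re-fit the model")
  if (sum(mu == min(mu)) > 1 || sum(mu == max(mu)) > 1)
    warning("tied cluster score means; breaking ties to the lower index")
  model$cluster_score_means <- mu
  model$avoidance_cluster <- which.min(mu)
  model$approach_cluster <- which.max(mu)
  model
}

#' Permutation null for cluster score means
#'
#' Behavioral score labels are randomly permuted over timepoints `n_perm`
#' times; each permutation yields the extreme (max and min) cluster mean
#' scores under the fixed cluster assignment. The observed approach
#' (avoidance) cluster mean is significant when it exceeds (falls below)
#' the 95th (5th) percentile of the corresponding null.
#'
#' @param model a labeled `cluster_model` (see [label_state_clusters()]).
#' @param scores per-timepoint scores.
#' @param n_perm permutations (default 100; below 20 the percentile is
#'   unstable and a warning is issued).
#' @param seed RNG seed.
#' @return list of class `state_null`: `null_max`, `null_min`, observed
#'   means, percentile positions and significance flags.
#' @export
cluster_permutation_null <- function(model, scores, n_perm = 100, seed = 1) {
  stopifnot(!is.null(model$approach_cluster))
  if (n_perm < 20) warning("n_perm < 20: null percentiles are unstable")
  ids <- seq_len(nrow(model$centroids))
  asg <- model$assignment
  nulls <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sc <- sample(scores)
    mu <- vapply(ids, function(k) mean(sc[asg == k]), numeric(1))
    c(max(mu), min(mu))
  }, numeric(2)))
  obs_app <- model$cluster_score_means[model$approach_cluster]
  obs_avd <- model$cluster_score_means[model$avoidance_cluster]
  structure(list(null_max = nulls[1, ], null_min = nulls[2, ],
                 observed_approach = obs_app, observed_avoidance = obs_avd,
                 approach_significant = obs_app > stats::quantile(nulls[1, ], 0.95, names = FALSE),
                 avoidance_significant = obs_avd < stats::quantile(nulls[2, ], 0.05, names = FALSE)),
            class = "state_null")
}

#' Transfer cluster centroids to a withheld assay
#'
#' Centroids fit on the training assay (co-registered cells only) classify
#' each test-assay timepoint by minimum Euclidean distance; transferred
#' approach/avoidance clusters keep their training identities, and the
#' separation of their test-assay score means is assessed by a two-sided
#' rank-sum test.
#'
#' @param model a labeled `cluster_model` trained on co-registered cells
#'   (row order = `coreg$cell_id_assay1`).
#' @param traces_test [trace_matrix()] of the withheld assay.
#' @param coreg a [coregistration_map()]; `cell_id_assay2` selects and
#'   orders the test cells.
#' @param scores_test per-timepoint scores in the withheld assay.
#' @return list of class `transfer_result`: `assignment`, per-cluster test
#'   score means, approach/avoidance means and the rank-sum p-value.
#' @export
transfer_clusters_across_assays <- function(model, traces_test, coreg,
                                            scores_test) {
  stopifnot(inherits(model, "cluster_model"))
  if (!nrow(coreg)) stop("empty co-registration map")
  idx <- match(coreg$cell_id_assay2, traces_test$cell_ids)
  if (anyNA(idx)) stop("co-registered cell(s) missing from the test traces")
  x <- t(traces_test$values[idx, , drop = FALSE])
  if (ncol(x) != ncol(model$centroids))
    stop("centroid dimensionality does not match the co-registered cells")
  d2 <- outer(rowSums(x^2), rep(1, nrow(model$centroids))) -
    2 * x %*% t(model$centroids) +
    outer(rep(1, nrow(x)), rowSums(model$centroids^2))
  asg <- max.col(-d2, ties.method = "first")
  mu <- vapply(seq_len(nrow(model$centroids)), function(k) {
    s <- scores_test[asg == k]
    if (length(s)) mean(s) else NA_real_
  }, numeric(1))
  app <- scores_test[asg == model$approach_cluster]
  avd <- scores_test[asg == model$avoidance_cluster]
  p <- if (length(app) && length(avd))
    suppressWarnings(stats::wilcox.test(app, avd, exact = FALSE)$p.value)
  else NA_real_
  structure(list(assignment = asg, cluster_score_means = mu,
                 approach_mean = mean(app), avoidance_mean = mean(avd),
                 p_ranksum = p),
            class = "transfer_result")
}

#' HMM-based avoidance/approach states
#'
#' Projects z-scored activity onto the top principal components explaining
#' at least `var_target` of total variance, fits a Gaussian HMM (default 4
#' states) by EM over seeded restarts (best log-likelihood kept), decodes
#' the state sequence by Viterbi, and exposes it in the same form as a
#' `cluster_model` so states can be labeled with
#' [label_state_clusters()] and analyzed identically.
#'
#' @param traces a z-scored [trace_matrix()].
#' @param n_states hidden states (default 4).
#' @param var_target minimum cumulative PC variance fraction (default 0.6).
#' @param n_restarts,max_iter,tol EM control.
#' @param seed base RNG seed.
#' @return list of class `c("hmm_state_model", "cluster_model")`:
#'   `assignment` (Viterbi path), `centroids` (emission means in PC space),
#'   `transmat`, `n_pcs`, `loglik_trace`, plus the PCA rotation.
#' @export
fit_hmm_states <- function(traces, n_states = 4, var_target = 0.6,
                           n_restarts = 10, max_iter = 500, tol = 1e-6,
                           seed = 1) {
  stopifnot(inherits(traces, "trace_matrix"))
  pc <- stats::prcomp(t(traces$values), center = TRUE, scale. = FALSE)
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  d <- which(cumvar >= var_target)[1]
  obs <- pc$x[, seq_len(d), drop = FALSE]
  fits <- lapply(seq_len(n_restarts), function(r)
    tryCatch(gaussian_hmm_em(obs, n_states, max_iter = max_iter, tol = tol,
                             seed = seed + 13L * r),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all HMM restarts failed")
  lls <- vapply(fits, function(f) f$loglik_trace[length(f$loglik_trace)], 0)
  best <- fits[[which.max(lls)]]
  structure(list(K = n_states, assignment = hmm_viterbi(best, obs),
                 centroids = best$means, transmat = best$transmat,
                 emission_vars = best$vars, n_pcs = d,
                 pc_rotation = pc$rotation[, seq_len(d), drop = FALSE],
                 loglik_trace = best$loglik_trace,
                 aic_table = data.frame(K = n_states, rss = NA, aic = NA),
                 rss = NA_real_, cell_ids = traces$cell_ids),
            class = c("hmm_state_model", "cluster_model"))
}
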