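# Arm-preference ensembles: categorization, scores, peri-event activity.

#' @noRd
zone_groups <- function(zones) {
  list(open1 = which(zones == "open1"), open2 = which(zones == "open2"),
       closed1 = which(zones == "closed1"), closed2 = which(zones == "closed2"))
}

#' Categorize open-, closed- and neither-arm-preferring cells
#'
#' A cell is open-arm-preferring when its activity in *each individual*
#' open arm is significantly greater than its pooled activity in the
#' closed arms (one-sided Wilcoxon rank-sum, p < `alpha`, both arms);
#' closed-arm-preferring by the mirrored rule; all remaining cells are
#' "neither". With `split = "40/60"` the first 40% of the session is used
#' for categorization and the last 60%, after a 10 s separation, is
#' withheld for independent activity estimates.
#'
#' Per-sample tests ignore temporal autocorrelation of the calcium signal;
#' this matches the categorization convention the scores are defined
#' against, and is the reason the split option exists.
#'
#' @param traces a z-scored [trace_matrix()] aligned to `zones`.
#' @param zones per-sample zone labels on the neural clock (center samples
#'   are excluded automatically).
#' @param split `NULL` (whole session) or `"40/60"`.
#' @param alpha significance level (raw, uncorrected by default).
#' @param fdr if TRUE, Benjamini-Hochberg-correct the four p-values per
#'   cell across cells before thresholding.
#' @return data.frame of class `ensemble_labels` with cell_id, category and
#'   the four arm p-values; attribute `withheld_idx` gives the evaluation
#'   samples under the split.
#' @export
categorize_arm_cells <- function(traces, zones, split = NULL, alpha = 0.05,
                                 fdr = FALSE) {
  stopifnot(inherits(traces, "trace_matrix"))
  n <- ncol(traces$values)
  stopifnot(length(zones) == n)
  cat_idx <- seq_len(n)
  withheld <- integer()
  if (!is.null(split)) {
    if (!identical(split, "40/60")) stop("only the '40/60' split is supported")
    n_cat <- floor(0.4 * n)
    gap <- ceiling(10 * traces$fs)
    cat_idx <- seq_len(n_cat)
    withheld <- seq.int(min(n_cat + gap + 1L, n), n)
  }
  z <- zones[cat_idx]
  g <- zone_groups(z)
  empty <- names(g)[vapply(g, length, 1L) == 0]
  if (length(empty))
    warning("arm(s) never visited: ", paste(empty, collapse = ", "),
            "; affected cells labeled neither")
  vals <- traces$values[, cat_idx, drop = FALSE]
  pooled_closed <- c(g$closed1, g$closed2)
  pooled_open <- c(g$open1, g$open2)
  p_onesided <- function(x, a, b) {
    if (!length(a) || !length(b)) return(NA_real_)
    suppressWarnings(stats::wilcox.test(x[a], x[b], alternative = "greater",
                                        exact = FALSE)$p.value)
  }
  res <- t(apply(vals, 1, function(x)
    c(p_open1 = p_onesided(x, g$open1, pooled_closed),
      p_open2 = p_onesided(x, g$open2, pooled_closed),
      p_closed1 = p_onesided(x, g$closed1, pooled_open),
      p_closed2 = p_onesided(x, g$closed2, pooled_open))))
  pmat <- res
  if (fdr) pmat <- apply(res, 2, stats::p.adjust, method = "BH")
  is_open <- !is.na(pmat[, 1]) & !is.na(pmat[, 2]) &
    pmat[, 1] < alpha & pmat[, 2] < alpha
  is_closed <- !is.na(pmat[, 3]) & !is.na(pmat[, 4]) &
    pmat[, 3] < alpha & pmat[, 4] < alpha
  category <- ifelse(is_open & !is_closed, "open",
                     ifelse(is_closed & !is_open, "closed", "neither"))
  out <- data.frame(cell_id = traces$cell_ids, category = category, res,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "withheld_idx") <- withheld
  attr(out, "split") <- split
  class(out) <- c("ensemble_labels", "data.frame")
  out
}

# Mann-Whitney AUC of `pos` vs `neg` via the rank-sum identity (handles
# ties as half-counts, identical to trapezoidal ROC integration over all
# observed thresholds).
#' @noRd
rank_auc <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Open arm preference score
#'
#' ROC analysis of single-cell activity predicting open- vs closed-arm
#' occupancy (center excluded): activity at or above a threshold predicts
#' "open", the threshold sweeps all observed activity values, and the
#' score is 2 * AUC - 1. Exactly +1 means open-arm activity is strictly
#' greater than all closed-arm activity; the score is invariant to
#' shifting and scaling of the cell's activity.
#'
#' @inheritParams categorize_arm_cells
#' @return data.frame with cell_id, auc and preference_score.
#' @export
open_arm_preference_score <- function(traces, zones) {
  stopifnot(inherits(traces, "trace_matrix"),
            length(zones) == ncol(traces$values))
  open_idx <- which(zones %in% c("open1", "open2"))
  closed_idx <- which(zones %in% c("closed1", "closed2"))
  if (!length(open_idx) || !length(closed_idx))
    stop("preference score undefined: an arm type was never visited")
  auc <- apply(traces$values, 1, function(x) rank_auc(x[open_idx], x[closed_idx]))
  data.frame(cell_id = traces$cell_ids, auc = auc,
             preference_score = 2 * auc - 1, row.names = NULL)
}

#' EPM score
#'
#' Contrast of between-arm-type vs within-arm-type activity differences:
#' A = 0.25 (|F_C1-F_O1| + |F_C1-F_O2| + |F_C2-F_O1| + |F_C2-F_O2|),
#' B = 0.5 (|F_C1-F_C2| + |F_O1-F_O2|), score = (A - B) / (A + B).
#' The maximum of 1.0 indicates identical activity within each arm type
#' (B = 0) but different activity between types; negative scores mean a
#' cell distinguishes same-type arms more than arm types. The degenerate
#' A = B = 0 case (all four means equal) is defined as 0: such a cell
#' carries no arm information.
#'
#' @param f_o1,f_o2,f_c1,f_c2 mean z-scored activity per arm (vectorized).
#' @return numeric vector of EPM scores in \[-1, 1\].
#' @export
epm_score <- function(f_o1, f_o2, f_c1, f_c2) {
  a <- 0.25 * (abs(f_c1 - f_o1) + abs(f_c1 - f_o2) +
                 abs(f_c2 - f_o1) + abs(f_c2 - f_o2))
  b <- 0.5 * (abs(f_c1 - f_c2) + abs(f_o1 - f_o2))
  ifelse(a + b == 0, 0, (a - b) / (a + b))
}

#' Per-cell arm mean activity, preference and EPM scores
#'
#' @inheritParams categorize_arm_cells
#' @return data.frame with per-cell arm means (f_o1, f_o2, f_c1, f_c2),
#'   auc, preference_score and epm_score. Arm means are NA (and the EPM
#'   score undefined) for arms never visited.
#' @export
arm_scores <- function(traces, zones) {
  g <- zone_groups(zones)
  mean_in <- function(x, idx) if (length(idx)) mean(x[idx]) else NA_real_
  m <- t(apply(traces$values, 1, function(x)
    c(f_o1 = mean_in(x, g$open1), f_o2 = mean_in(x, g$open2),
      f_c1 = mean_in(x, g$closed1), f_c2 = mean_in(x, g$closed2))))
  pref <- open_arm_preference_score(traces, zones)
  data.frame(cell_id = traces$cell_ids, m, auc = pref$auc,
             preference_score = pref$preference_score,
             epm_score = epm_score(m[, "f_o1"], m[, "f_o2"],
                                   m[, "f_c1"], m[, "f_c2"]),
             row.names = NULL)
}

#' Onset-aligned peri-event activity and delta dF/F
#'
#' Aligns each cell's activity to behavior onsets, averages across events,
#' and computes the change in mean activity: mean over `post_window` minus
#' mean over `pre_window` (defaults \[0, 2.5\] vs \[-2.5, 0\] s; for head
#' dips use `pre_window = c(-5, -2.5)`). Events without full flanking data
#' are dropped. With `exclude_label` set, events of `label` whose onset
#' falls within `exclude_s` seconds after an `exclude_label` onset are
#' excluded, reducing confounds from slow calcium decay between opposing
#' behaviors.
#'
#' @param traces a z-scored [trace_matrix()].
#' @param intervals a [behavior_intervals()] table.
#' @param label behavior to align to.
#' @param window trace window around onset, seconds.
#' @param pre_window,post_window windows for the activity change, seconds
#'   relative to onset.
#' @param exclude_label,exclude_s cross-exclusion rule (e.g. escapes and
#'   freezes within 10 s of each other).
#' @return list of class `peri_event_result`: `mean_trace` (cells x window
#'   samples), `delta` (per cell), `times`, `n_events`, `label`.
#' @export
peri_event_analysis <- function(traces, intervals, label,
                                window = c(-5, 5),
                                pre_window = c(-2.5, 0),
                                post_window = c(0, 2.5),
                                exclude_label = NULL, exclude_s = 10) {
  stopifnot(inherits(traces, "trace_matrix"))
  fs <- traces$fs
  ev <- intervals_of(intervals, label)
  if (!nrow(ev)) stop("no '", label, "' events to align to")
  if (!is.null(exclude_label)) {
    other <- intervals_of(intervals, exclude_label)
    if (nrow(other)) {
      bad <- vapply(ev$onset, function(o)
        any(o > other$onset & o <= other$onset + exclude_s), logical(1))
      ev <- ev[!bad, , drop = FALSE]
    }
  }
  rel <- seq(round(window[1] * fs), round(window[2] * fs))
  n <- ncol(traces$values)
  onsets <- floor(ev$onset * fs) + 1L
  usable <- onsets + rel[1] >= 1L & onsets + rel[length(rel)] <= n
  onsets <- onsets[usable]
  if (!length(onsets)) stop("no usable '", label, "' events (flanking data)")
  acc <- matrix(0, nrow(traces$values), length(rel))
  for (o in onsets) acc <- acc + traces$values[, o + rel, drop = FALSE]
  mean_trace <- acc / length(onsets)
  times <- rel / fs
  pre_i <- which(times >= pre_window[1] - 1e-9 & times < pre_window[2] - 1e-9)
  post_i <- which(times >= post_window[1] - 1e-9 & times < post_window[2] - 1e-9)
  delta <- rowMeans(mean_trace[, post_i, drop = FALSE]) -
    rowMeans(mean_trace[, pre_i, drop = FALSE])
  structure(list(mean_trace = mean_trace, delta = delta, times = times,
                 n_events = length(onsets), label = label,
                 cell_ids = traces$cell_ids),
            class = "peri_event_result")
}

#' Ensemble means of a peri-event result
#'
#' @param pe a `peri_event_result`.
#' @param categories per-cell category labels (e.g. from
#'   [categorize_arm_cells()]).
#' @return data.frame with per-category mean and SEM of the activity change.
#' @export
peri_event_ensemble <- function(pe, categories) {
  stopifnot(length(categories) == length(pe$delta))
  cats <- sort(unique(categories))
  do.call(rbind, lapply(cats, function(cc) {
    d <- pe$delta[categories == cc]
    data.frame(category = cc, n_cells = length(d), delta_mean = mean(d),
               delta_sem = stats::sd(d) / sqrt(length(d)))
  }))
}

#' Activity correlations
#'
#' Per-cell Pearson correlations of activity with behavioral covariates
#' (speed, location index, ...), and across-cell correlations of per-arm
#' mean activity (open1 vs open2; open vs closed).
#'
#' @param traces a z-scored [trace_matrix()].
#' @param zones per-sample zone labels (NULL to skip arm means).
#' @param covariates data.frame of per-sample numeric regressors.
#' @return list with `per_cell` (data.frame of correlations, NA for
#'   zero-variance regressors) and `across_cells` (open1 vs open2, open vs
#'   closed correlations over cells).
#' @export
activity_correlations <- function(traces, zones = NULL, covariates = NULL) {
  out <- list()
  if (!is.null(covariates)) {
    per <- data.frame(cell_id = traces$cell_ids, row.names = NULL)
    for (nm in names(covariates)) {
      y <- covariates[[nm]]
      if (stats::sd(y) == 0) {
        per[[paste0("r_", nm)]] <- NA_real_
        message("covariate '", nm, "' has zero variance; correlation undefined")
      } else {
        per[[paste0("r_", nm)]] <- apply(traces$values, 1, stats::cor, y = y)
      }
    }
    out$per_cell <- per
  }
  if (!is.null(zones)) {
    g <- zone_groups(zones)
    mo1 <- rowMeans(traces$values[, g$open1, drop = FALSE])
    mo2 <- rowMeans(traces$values[, g$open2, drop = FALSE])
    mc <- rowMeans(traces$values[, c(g$closed1, g$closed2), drop = FALSE])
    mo <- rowMeans(traces$values[, c(g$open1, g$open2), drop = FALSE])
    out$across_cells <- list(r_open1_open2 = stats::cor(mo1, mo2),
                             r_open_closed = stats::cor(mo, mc))
  }
  out
}

#' Occupancy-normalized spatial activity map
#'
#' Mean z-scored activity per spatial bin; bins visited fewer than
#' `min_occupancy` samples are masked (NA).
#'
#' @param traces a z-scored [trace_matrix()].
#' @param xy data.frame with per-sample `x`, `y` positions (neural clock).
#' @param bin_cm bin side length, cm.
#' @param min_occupancy minimum samples per bin.
#' @return list with `maps` (array x-bins x y-bins x cells), `occupancy`,
#'   `x_breaks`, `y_breaks`.
#' @export
spatial_activity_map <- function(traces, xy, bin_cm = 2, min_occupancy = 3) {
  stopifnot(nrow(xy) == ncol(traces$values))
  xb <- seq(floor(min(xy$x)), ceiling(max(xy$x)) + bin_cm, by = bin_cm)
  yb <- seq(floor(min(xy$y)), ceiling(max(xy$y)) + bin_cm, by = bin_cm)
  ix <- findInterval(xy$x, xb, rightmost.closed = TRUE)
  iy <- findInterval(xy$y, yb, rightmost.closed = TRUE)
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  bin <- (iy - 1L) * nx + ix
  occ_tab <- tabulate(bin, nbins = nx * ny)
  occupancy <- matrix(occ_tab, nx, ny)
  nc <- nrow(traces$values)
  maps <- array(NA_real_, c(nx, ny, nc),
                dimnames = list(NULL, NULL, traces$cell_ids))
  sums <- matrix(0, nx * ny, nc)
  for (b in unique(bin))
    sums[b, ] <- rowSums(traces$values[, bin == b, drop = FALSE])
  means <- sweep(sums, 1, pmax(occ_tab, 1), `/`)
  means[occ_tab < min_occupancy, ] <- NA_real_
  for (k in seq_len(nc)) maps[, , k] <- matrix(means[, k], nx, ny)
  list(maps = maps, occupancy = occupancy, x_breaks = xb, y_breaks = yb)
}
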