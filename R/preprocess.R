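# Trace conditioning. Pipeline order is fixed: artifact suppression (raw
# traces) -> variance thresholding -> z-scoring, then alignment to the
# behavioral clock.

#' Write a synthetic session to disk
#'
#' Writes the trace matrix as wide CSV (cell_id + one column per sample),
#' the pose as a keypoint-tracker dialect CSV (three header rows: scorer /
#' bodyparts / coords, with x, y, likelihood per keypoint), the
#' co-registration map as a two-column CSV, the ground truth as JSON and a
#' small session meta JSON (sampling rates, assay). Round-trips through
#' [load_session()] within float-write precision.
#'
#' @param session a list from [simulate_session()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param coreg optional [coregistration_map()] to write alongside.
#' @return invisibly, the named character vector of file paths.
#' @export
write_fixture_bundle <- function(session, dir, prefix = "session", coreg = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  paths <- c(traces = file.path(dir, paste0(prefix, "_traces.csv")),
             pose = file.path(dir, paste0(prefix, "_pose.csv")),
             meta = file.path(dir, paste0(prefix, "_meta.json")),
             truth = file.path(dir, paste0(prefix, "_truth.json")))
  tr <- session$traces
  df <- data.frame(cell_id = tr$cell_ids,
                   format(tr$values, digits = 17, scientific = TRUE,
                          trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("cell_id", paste0("t", seq_len(ncol(tr$values))))
  utils::write.csv(df, paths["traces"], row.names = FALSE, quote = FALSE)

  pd <- session$pose$data
  kps <- unique(sub("_(x|y)$", "", grep("_(x|y)$", names(pd), value = TRUE)))
  kps <- setdiff(kps, "centroid")    # derived, not a tracked keypoint
  hdr1 <- c("scorer", rep("synthetic", 3 * length(kps)))
  hdr2 <- c("bodyparts", rep(kps, each = 3))
  hdr3 <- c("coords", rep(c("x", "y", "likelihood"), length(kps)))
  body <- matrix("", nrow(pd), 3 * length(kps))
  for (i in seq_along(kps)) {
    body[, 3 * i - 2] <- format(pd[[paste0(kps[i], "_x")]], digits = 17, trim = TRUE)
    body[, 3 * i - 1] <- format(pd[[paste0(kps[i], "_y")]], digits = 17, trim = TRUE)
    lk <- pd[[paste0(kps[i], "_likelihood")]] %||% rep(1, nrow(pd))
    body[, 3 * i] <- format(lk, trim = TRUE)
  }
  con <- file(paths["pose"], "w")
  writeLines(c(paste(hdr1, collapse = ","), paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ",")), con)
  utils::write.table(cbind(seq_len(nrow(pd)) - 1L, body), con, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(con)

  jsonlite::write_json(list(fs_hz = tr$fs, fps = session$pose$fps,
                            assay_kind = session$geometry$assay_kind),
                       paths["meta"], auto_unbox = TRUE, digits = NA)
  tru <- session$truth
  jsonlite::write_json(list(cell_category = tru$cell_category,
                            state_sequence = tru$state_sequence,
                            zone_sequence = tru$zone_sequence,
                            planted_event_table = as.data.frame(tru$planted_event_table),
                            fps = tru$fps, assay_kind = tru$assay_kind,
                            session_length = tru$session_length,
                            seed = tru$seed),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  if (!is.null(coreg)) {
    paths["coreg"] <- file.path(dir, paste0(prefix, "_coreg.csv"))
    utils::write.csv(as.data.frame(coreg), paths["coreg"], row.names = FALSE,
                     quote = FALSE)
  }
  invisible(paths)
}

#' @rdname load_session
#' @export
read_coregistration <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("co-registration CSV needs two columns")
  coregistration_map(df[[1]], df[[2]])
}

#' Load a session from disk
#'
#' Reads a wide trace CSV (first column `cell_id`) and a keypoint-tracker
#' CSV (three header rows: scorer, bodyparts, coords). Keypoint gaps with
#' likelihood below `likelihood_min` are linearly interpolated up to
#' `max_gap` frames; longer gaps are an error.
#'
#' @param trace_path,pose_path file paths.
#' @param geometry an [assay_geometry()].
#' @param fs,fps neural and behavioral sampling rates (Hz).
#' @param likelihood_min tracker confidence below which a frame counts as a
#'   gap.
#' @param max_gap longest interpolable gap, frames.
#' @return list with `traces` ([trace_matrix()]) and `pose`
#'   ([pose_track()]).
#' @export
load_session <- function(trace_path, pose_path, geometry, fs = 7.5, fps = 30,
                         likelihood_min = 0.9, max_gap = 10) {
  df <- utils::read.csv(trace_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "cell_id") stop("trace CSV must start with a cell_id column")
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric trace values in ", trace_path)
  traces <- trace_matrix(vals, fs = fs, cell_ids = df$cell_id)

  hdr <- utils::read.csv(pose_path, header = FALSE, nrows = 3,
                         stringsAsFactors = FALSE)
  body <- utils::read.csv(pose_path, header = FALSE, skip = 3)
  parts <- as.character(unlist(hdr[2, -1]))
  coords <- as.character(unlist(hdr[3, -1]))
  need <- c("nose", "ear_l", "ear_r", "tailbase")
  miss <- setdiff(need, unique(parts))
  if (length(miss)) stop("pose file missing keypoint(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (kp in unique(parts)) {
    for (cc in c("x", "y", "likelihood")) {
      j <- which(parts == kp & coords == cc) + 1L
      if (length(j) != 1L) next
      col <- as.numeric(body[[j]])
      nm <- if (cc == "likelihood") paste0(kp, "_likelihood") else paste0(kp, "_", cc)
      out[[nm]] <- col
    }
  }
  pd <- as.data.frame(out)
  # gap interpolation driven by tracker confidence
  for (kp in unique(parts)) {
    lk <- pd[[paste0(kp, "_likelihood")]]
    if (is.null(lk)) next
    bad <- lk < likelihood_min
    if (!any(bad)) next
    runs <- true_runs(bad)
    if (any(runs$end - runs$start + 1L > max_gap))
      stop("pose gap longer than ", max_gap, " frames for keypoint ", kp)
    for (cc in c("_x", "_y")) {
      v <- pd[[paste0(kp, cc)]]
      v[bad] <- NA
      pd[[paste0(kp, cc)]] <- stats::approx(seq_along(v), v, seq_along(v),
                                            rule = 2)$y
    }
  }
  list(traces = traces, pose = pose_track(pd, fps = fps, geometry = geometry))
}

#' Suppress large-variance artifact components
#'
#' PCA across cells identifies components carrying at least
#' `var_threshold` of total variance; flagged components (a manual index
#' list, or an automatic slow-power criterion) are excluded from the
#' reconstruction. Artifacts such as shared bleaching are large in
#' magnitude and spread over many neurons, so they surface as
#' high-variance components dominated by very low frequencies; the
#' automatic criterion flags a candidate when more than `slow_frac` of its
#' projected power lies below `slow_hz` (a reproducible surrogate for
#' visual inspection, which the original workflow used).
#'
#' @param traces a raw (not z-scored) [trace_matrix()].
#' @param flagged_pcs optional integer vector of component indices to
#'   remove; overrides the automatic criterion.
#' @param var_threshold candidate variance fraction (default 0.05).
#' @param slow_hz,slow_frac automatic criterion parameters.
#' @return the reconstructed [trace_matrix()], with attribute `report`
#'   (data.frame of candidate components, variance fractions, and whether
#'   each was removed).
#' @export
suppress_artifact_components <- function(traces, flagged_pcs = NULL,
                                         var_threshold = 0.05,
                                         slow_hz = 0.01, slow_frac = 0.6) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (traces$is_zscored) stop("artifact suppression must precede z-scoring")
  x <- t(traces$values)                       # time x cells
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  cand <- which(varfrac >= var_threshold)
  if (!is.null(flagged_pcs)) {
    if (length(flagged_pcs) && (min(flagged_pcs) < 1 || max(flagged_pcs) > ncol(pc$x)))
      stop("flagged PC index out of range")
    removed <- as.integer(flagged_pcs)
  } else {
    removed <- integer()
    for (k in cand) {
      s <- pc$x[, k]
      pw <- Mod(stats::fft(s - mean(s)))^2
      nf <- length(s)
      freq <- (seq_len(nf) - 1) / nf * traces$fs
      half <- freq <= traces$fs / 2
      frac_slow <- sum(pw[half & freq < slow_hz]) / sum(pw[half])
      if (is.finite(frac_slow) && frac_slow > slow_frac) removed <- c(removed, k)
    }
  }
  report <- data.frame(pc = seq_along(varfrac), var_frac = varfrac,
                       candidate = seq_along(varfrac) %in% cand,
                       removed = seq_along(varfrac) %in% removed)
  if (length(removed) == ncol(pc$x))
    warning("all principal components removed; reconstruction is the cell means")
  keep <- setdiff(seq_len(ncol(pc$x)), removed)
  recon <- if (length(removed) == 0L) x else
    pc$x[, keep, drop = FALSE] %*% t(pc$rotation[, keep, drop = FALSE]) +
    matrix(pc$center, nrow(x), ncol(x), byrow = TRUE)
  out <- trace_matrix(t(recon), fs = traces$fs, cell_ids = traces$cell_ids)
  attr(out, "report") <- report
  out
}

# Elbow of a decreasing curve: the point with maximum perpendicular
# distance to the chord joining the first and last points, computed on
# axes normalized to [0, 1] so neither index nor variance scale dominates.
#' @noRd
elbow_index <- function(y) {
  n <- length(y)
  rng <- y[1] - y[n]
  if (n < 3 || rng <= 0) return(list(index = 1L, distance = 0))
  xs <- (seq_len(n) - 1) / (n - 1)
  ys <- (y - y[n]) / rng
  v <- c(xs[n] - xs[1], ys[n] - ys[1])
  v <- v / sqrt(sum(v^2))
  dist <- abs(xs * v[2] - (ys - 1) * v[1])
  i <- which.max(dist)
  # at a sharp cliff the farthest point sits just below the chord, on the
  # low-variance side; the elbow cell is the last one before the drop
  if (ys[i] < 1 - xs[i] && i > 1L) i <- i - 1L
  list(index = i, distance = max(dist))
}

#' Variance thresholding with a reference cell
#'
#' Cell variances are sorted in decreasing order; the reference cell sits
#' at the elbow of that curve (maximum perpendicular distance to the chord
#' from the first to the last point). When no clear elbow exists (the
#' maximal chord distance is below `min_elbow_frac` of the curve's range),
#' the highest-variance cell is the reference. Cells with variance below
#' 10% of the reference cell's variance are discarded; the reference cell
#' itself is never discarded.
#'
#' @param traces a [trace_matrix()] with at least 3 cells.
#' @param ratio_min discard threshold relative to the reference variance.
#' @param min_elbow_frac curvature threshold deciding whether an elbow is
#'   "obvious".
#' @return the filtered [trace_matrix()]; attribute `report` records the
#'   reference cell, its variance and the discarded cell ids.
#' @export
variance_filter <- function(traces, ratio_min = 0.1, min_elbow_frac = 0.05) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (nrow(traces$values) < 3) stop("variance filtering needs at least 3 cells")
  v <- apply(traces$values, 1, stats::var)
  ord <- order(v, decreasing = TRUE)
  vs <- v[ord]
  eb <- elbow_index(vs)
  ref_pos <- if (eb$distance < min_elbow_frac) 1L else eb$index
  ref_var <- vs[ref_pos]
  keep <- v >= ratio_min * ref_var
  keep[ord[ref_pos]] <- TRUE                  # reference never discarded
  if (!any(keep)) stop("variance filter removed all cells")
  out <- trace_matrix(traces$values[keep, , drop = FALSE], fs = traces$fs,
                      cell_ids = traces$cell_ids[keep],
                      is_zscored = traces$is_zscored)
  attr(out, "report") <- list(reference_cell = traces$cell_ids[ord[ref_pos]],
                              reference_variance = ref_var,
                              discarded = traces$cell_ids[!keep])
  out
}

#' z-Score traces
#'
#' Each cell is z-scored once over the whole session: (x - mu) / sigma with
#' the session-wide mean and population SD. Already-z-scored input is
#' refused rather than silently re-transformed.
#'
#' @param traces a [trace_matrix()].
#' @return the z-scored [trace_matrix()] (`is_zscored = TRUE`).
#' @export
zscore_traces <- function(traces) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (traces$is_zscored)
    stop("traces are already z-scored; z-scoring is applied exactly once")
  mu <- rowMeans(traces$values)
  n <- ncol(traces$values)
  sigma <- sqrt(rowMeans((traces$values - mu)^2))   # population SD
  zero <- sigma <= 0
  if (any(zero))
    stop("zero-variance cell(s): ", paste(traces$cell_ids[zero], collapse = ", "))
  trace_matrix((traces$values - mu) / sigma, fs = traces$fs,
               cell_ids = traces$cell_ids, is_zscored = TRUE)
}

#' Align behavioral channels to the neural clock
#'
#' Downsamples per-frame behavioral channels by the integer fps/fs ratio:
#' continuous channels by block averaging, logical channels by
#' any-within-block, character/factor channels by block majority. Trailing
#' partial blocks are dropped and the traces cropped to the common length.
#'
#' @param traces a [trace_matrix()].
#' @param behavior data.frame of per-frame channels (or a [pose_track()],
#'   in which case its coordinate columns are aligned).
#' @param fps behavioral frame rate.
#' @return list with `traces` (cropped) and `behavior` (downsampled
#'   data.frame, one row per neural sample).
#' @export
align_timebases <- function(traces, behavior, fps = 30) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (inherits(behavior, "pose_track")) {
    fps <- behavior$fps
    behavior <- behavior$data
  }
  ratio <- fps / traces$fs
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("behavior fps must be an integer multiple of the neural rate")
  ratio <- as.integer(round(ratio))
  n_blocks <- nrow(behavior) %/% ratio
  n <- min(n_blocks, ncol(traces$values))
  ds <- lapply(behavior, function(col) {
    m <- matrix(col[seq_len(n * ratio)], nrow = ratio)
    if (is.logical(col)) apply(m, 2, any)
    else if (is.numeric(col)) colMeans(m)
    else apply(m, 2, function(b) names(which.max(table(b))))
  })
  out_b <- as.data.frame(ds, stringsAsFactors = FALSE)
  out_t <- trace_matrix(traces$values[, seq_len(n), drop = FALSE],
                        fs = traces$fs, cell_ids = traces$cell_ids,
                        is_zscored = traces$is_zscored)
  list(traces = out_t, behavior = out_b)
}
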