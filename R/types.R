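#' Calcium trace matrix
#'
#' Container for a cells x timepoints dF/F (or z-scored) matrix together with
#' its sampling rate and cell identifiers. All neural computation in the
#' package operates on this object.
#'
#' @param values numeric matrix, cells in rows, timepoints in columns.
#' @param fs sampling rate in Hz (7.5 for miniscope recordings).
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   `cell_1 ... cell_n`.
#' @param is_zscored logical flag; set by [zscore_traces()].
#' @return An object of class `trace_matrix`.
#' @export
trace_matrix <- function(values, fs, cell_ids = NULL, is_zscored = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("trace values must be numeric")
  if (anyNA(values)) stop("trace matrix contains missing values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar (Hz)")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(values)) stop("cell_ids length must match rows of values")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  rownames(values) <- cell_ids
  structure(list(values = values, fs = fs, cell_ids = cell_ids,
                 is_zscored = isTRUE(is_zscored)),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d cells x %d timepoints @ %g Hz (%.1f s)%s\n",
              nrow(x$values), ncol(x$values), x$fs, ncol(x$values) / x$fs,
              if (x$is_zscored) ", z-scored" else ""))
  invisible(x)
}

#' @export
dim.trace_matrix <- function(x) dim(x$values)

#' Per-frame pose track
#'
#' Keypoint coordinates (cm) for nose, left/right ear and tailbase at the
#' behavioral frame rate, plus (rat assay) the rat body-center position.
#'
#' @param data data.frame with columns `<keypoint>_x`, `<keypoint>_y` for
#'   keypoints nose, ear_l, ear_r, tailbase (and rat for the rat assay);
#'   optional `<keypoint>_likelihood` columns from the pose tracker.
#' @param fps frame rate in Hz (30 for the video capture used here).
#' @param geometry an [assay_geometry()] object.
#' @return An object of class `pose_track`.
#' @export
pose_track <- function(data, fps = 30, geometry) {
  data <- as.data.frame(data)
  need <- as.vector(outer(c("nose", "ear_l", "ear_r", "tailbase"),
                          c("_x", "_y"), paste0))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("pose track missing keypoint columns: ", paste(miss, collapse = ", "))
  if (geometry$assay_kind == "RAT" && !all(c("rat_x", "rat_y") %in% names(data)))
    stop("RAT assay pose track requires rat_x/rat_y columns")
  if (fps <= 0) stop("fps must be positive")
  structure(list(data = data, fps = fps, geometry = geometry,
                 n_frames = nrow(data)),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames @ %g fps (%.1f s), assay %s\n",
              x$n_frames, x$fps, x$n_frames / x$fps, x$geometry$assay_kind))
  invisible(x)
}

#' Labeled behavior intervals
#'
#' Onset/offset event table for detected (or planted) behaviors.
#'
#' @param label character vector in freeze, approach, escape, head_dip,
#'   rat_movement.
#' @param onset,offset numeric vectors, seconds; `onset < offset` elementwise.
#' @param meta optional data.frame of per-event annotations (e.g. rat-movement
#'   direction angle).
#' @return data.frame of class `behavior_intervals` with columns label,
#'   onset, offset plus any meta columns.
#' @export
behavior_intervals <- function(label = character(), onset = numeric(),
                               offset = numeric(), meta = NULL) {
  out <- data.frame(label = as.character(label), onset = as.numeric(onset),
                    offset = as.numeric(offset), stringsAsFactors = FALSE)
  if (nrow(out) && any(out$onset >= out$offset)) stop("interval onsets must precede offsets")
  known <- c("freeze", "approach", "escape", "head_dip", "rat_movement")
  if (nrow(out) && !all(out$label %in% known))
    stop("unknown behavior label(s): ", paste(setdiff(out$label, known), collapse = ", "))
  if (!is.null(meta)) out <- cbind(out, as.data.frame(meta))
  # same-label intervals must not overlap
  for (lb in unique(out$label)) {
    sub <- out[out$label == lb, ]
    sub <- sub[order(sub$onset), ]
    if (nrow(sub) > 1L && any(sub$onset[-1L] < sub$offset[-nrow(sub)]))
      stop("overlapping '", lb, "' intervals")
  }
  class(out) <- c("behavior_intervals", "data.frame")
  out
}

#' Combine behavior-interval tables
#'
#' Row-binds interval tables that may carry different meta columns (missing
#' meta filled with NA), sorted by onset.
#'
#' @param ... [behavior_intervals()] objects.
#' @return A combined [behavior_intervals()] data.frame.
#' @export
combine_intervals <- function(...) {
  parts <- Filter(function(x) nrow(x) > 0, list(...))
  if (!length(parts)) return(behavior_intervals())
  cols <- unique(unlist(lapply(parts, names)))
  parts <- lapply(parts, function(p) {
    for (cl in setdiff(cols, names(p))) p[[cl]] <- NA
    as.data.frame(p)[, cols, drop = FALSE]
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("behavior_intervals", "data.frame")
  out
}

#' @noRd
intervals_of <- function(intervals, label) {
  intervals[intervals$label == label, , drop = FALSE]
}

# Per-frame logical indicator of interval occupancy.
#' @noRd
interval_indicator <- function(intervals, n_frames, fps, label = NULL) {
  if (!is.null(label)) intervals <- intervals_of(intervals, label)
  ind <- rep(FALSE, n_frames)
  if (!nrow(intervals)) return(ind)
  for (i in seq_len(nrow(intervals))) {
    a <- time_to_frame(intervals$onset[i], fps)
    b <- min(n_frames, ceiling(intervals$offset[i] * fps))
    if (a <= b) ind[a:b] <- TRUE
  }
  ind
}

#' Cross-session cell co-registration map
#'
#' One-to-one pairing of cell identifiers between two sessions, as produced
#' by cross-session registration tools (consumed, never computed, here).
#'
#' @param cell_id_assay1,cell_id_assay2 character vectors of equal length,
#'   no duplicates on either side.
#' @return data.frame of class `coregistration_map`.
#' @export
coregistration_map <- function(cell_id_assay1, cell_id_assay2) {
  if (length(cell_id_assay1) != length(cell_id_assay2))
    stop("co-registration columns must have equal length")
  if (anyDuplicated(cell_id_assay1) || anyDuplicated(cell_id_assay2))
    stop("co-registration map must be one-to-one")
  out <- data.frame(cell_id_assay1 = as.character(cell_id_assay1),
                    cell_id_assay2 = as.character(cell_id_assay2),
                    stringsAsFactors = FALSE)
  class(out) <- c("coregistration_map", "data.frame")
  out
}
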