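# Encoding model: behaviors and kinematics convolved with a log-time
# raised-cosine basis, Gaussian-identity least-squares fit per cell.

#' Log-time raised cosine basis
#'
#' Bump functions on log-compressed time: with x = log(t + b + eps) and
#' phase centers phi_j = log(b + eps) + (j - 1) * pi / 2, the j-th basis is
#' f_j(x) = 0.5 * (cos(pi * x - phi_j) + 1) on phi_j/pi - 1 < x <= phi_j/pi + 1
#' and zero outside. Each basis peaks at 1 (at x = phi_j / pi), adjacent
#' peaks are spaced pi/2 in phase (0.5 in x), and early bases are narrow in
#' t while later ones stretch — fine temporal resolution near the event,
#' coarse further away.
#'
#' @param n_bases number of bases J.
#' @param b,eps log-time offsets, seconds. Defaults (J = 5, b = 0.25,
#'   eps = 1e-3) put the last peak near 4.5 s so the basis set covers the
#'   5 s response window at the neural rate.
#' @param t_max window length, seconds.
#' @param fs sampling rate, Hz.
#' @return matrix (time samples x J) with attribute `t_grid`; columns are
#'   the kernels evaluated on t in \[0, t_max\].
#' @export
raised_cosine_basis <- function(n_bases = 5, b = 0.25, eps = 1e-3,
                                t_max = 5, fs = 7.5) {
  stopifnot(n_bases >= 1, b + eps > 0, t_max > 0)
  t_grid <- seq(0, t_max, by = 1 / fs)
  x <- log(t_grid + b + eps)
  phi <- log(b + eps) + (seq_len(n_bases) - 1) * pi / 2
  B <- vapply(phi, function(ph) {
    f <- 0.5 * (cos(pi * x - ph) + 1)
    f[x <= ph / pi - 1 | x > ph / pi + 1] <- 0
    f
  }, numeric(length(x)))
  dead <- colSums(B > 0) == 0
  if (any(dead))
    stop("basis support entirely outside the [0, ", t_max, "] s window: ",
         paste(which(dead), collapse = ", "))
  colnames(B) <- paste0("rc", seq_len(n_bases))
  attr(B, "t_grid") <- t_grid
  B
}

# Causal convolution of a signal with a kernel (response follows the
# input); `mirror = TRUE` time-reverses the kernel so the response
# precedes the input (anticipatory lobes).
#' @noRd
conv_causal <- function(x, k, mirror = FALSE) {
  n <- length(x)
  if (mirror) return(rev(conv_causal(rev(x), k)))
  stats::convolve(x, rev(k), type = "open")[seq_len(n)]
}

#' Build the encoding design matrix
#'
#' Binary behavior indicators are convolved with the raised-cosine basis
#' both forward (responses up to `t_max` s after the event, extended over
#' the whole event duration) and mirrored (anticipatory responses up to
#' `t_max` s before onset), so behaviors can shape activity from 5 s before
#' onset to 5 s after offset. Continuous kinematic channels are z-scored
#' and convolved with forward bases only (responses follow the kinematics
#' within 5 s). An intercept is added at fit time, not here.
#'
#' @param events a [behavior_intervals()] table (labels become channels),
#'   or NULL.
#' @param kinematics data.frame of per-sample continuous channels, or NULL.
#' @param n_timepoints number of neural samples.
#' @param fs neural sampling rate.
#' @param basis a matrix from [raised_cosine_basis()] (default basis if
#'   NULL).
#' @return numeric matrix (n_timepoints x m) with named columns
#'   `<channel>.fwd<j>` / `<channel>.pre<j>`; attribute `channels` lists
#'   the channel of each column.
#' @export
build_design_matrix <- function(events = NULL, kinematics = NULL,
                                n_timepoints, fs = 7.5, basis = NULL) {
  if (is.null(basis)) basis <- raised_cosine_basis(fs = fs)
  cols <- list()
  channels <- character()
  if (!is.null(events) && nrow(events)) {
    for (lb in unique(events$label)) {
      ind <- as.numeric(interval_indicator(events, n_timepoints, fs, lb))
      for (j in seq_len(ncol(basis))) {
        cols[[paste0(lb, ".fwd", j)]] <- conv_causal(ind, basis[, j])
        cols[[paste0(lb, ".pre", j)]] <- conv_causal(ind, basis[, j], mirror = TRUE)
        channels <- c(channels, lb, lb)
      }
    }
  }
  if (!is.null(kinematics)) {
    for (nm in names(kinematics)) {
      v <- kinematics[[nm]]
      stopifnot(length(v) == n_timepoints)
      s <- stats::sd(v)
      if (s == 0) { warning("kinematic channel '", nm, "' is constant; omitted"); next }
      v <- (v - mean(v)) / s
      for (j in seq_len(ncol(basis))) {
        cols[[paste0(nm, ".fwd", j)]] <- conv_causal(v, basis[, j])
        channels <- c(channels, nm)
      }
    }
  }
  if (!length(cols)) stop("no design columns: provide events and/or kinematics")
  X <- do.call(cbind, cols)
  attr(X, "channels") <- channels
  X
}

#' Fit the encoding GLM per cell
#'
#' Gaussian-identity model x = beta_1 y_1 + ... + beta_m y_m + c per cell,
#' fit by minimizing mean-square error on the training rows. Singular
#' designs fall back to a small ridge penalty with a warning. The
#' per-channel summary weight is the mean of that channel's basis
#' coefficients.
#'
#' @param traces a z-scored [trace_matrix()].
#' @param design matrix from [build_design_matrix()].
#' @param split optional factor from [make_interleaved_split()]; when given,
#'   the fit uses training rows and R-squared is reported for both sets.
#' @return list of class `glm_fit`: `beta` (cells x columns), `intercept`,
#'   `summary_weights` (cells x channels), `r2_train`, `r2_test`.
#' @export
fit_glm_encoding <- function(traces, design, split = NULL) {
  stopifnot(inherits(traces, "trace_matrix"),
            nrow(design) == ncol(traces$values))
  rows <- if (is.null(split)) seq_len(nrow(design)) else which(split == "train")
  te_rows <- if (is.null(split)) integer() else which(split == "test")
  X <- cbind(`(intercept)` = 1, design)
  Y <- t(traces$values)
  qr_x <- qr(X[rows, , drop = FALSE])
  if (qr_x$rank < ncol(X) || length(rows) <= ncol(X)) {
    warning("singular or underdetermined design; using a small ridge penalty")
    xtx <- crossprod(X[rows, , drop = FALSE])
    beta_all <- solve(xtx + diag(1e-6 * mean(diag(xtx)), ncol(X)),
                      crossprod(X[rows, , drop = FALSE], Y[rows, , drop = FALSE]))
  } else {
    beta_all <- qr.coef(qr_x, Y[rows, , drop = FALSE])
  }
  pred <- X %*% beta_all
  r2 <- function(idx) {
    if (!length(idx)) return(NULL)
    ss_res <- colSums((Y[idx, , drop = FALSE] - pred[idx, , drop = FALSE])^2)
    mu <- colMeans(Y[idx, , drop = FALSE])
    ss_tot <- colSums(sweep(Y[idx, , drop = FALSE], 2, mu)^2)
    1 - ss_res / ss_tot
  }
  channels <- attr(design, "channels")
  beta <- t(beta_all)[, -1, drop = FALSE]
  sw <- vapply(unique(channels), function(ch)
    rowMeans(beta[, channels == ch, drop = FALSE]), numeric(nrow(beta)))
  if (is.null(dim(sw))) sw <- matrix(sw, nrow = 1, dimnames = list(NULL, unique(channels)))
  structure(list(beta = beta, intercept = as.numeric(t(beta_all)[, 1]),
                 summary_weights = sw, cell_ids = traces$cell_ids,
                 r2_train = r2(rows), r2_test = r2(te_rows)),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d cells, %d design columns; mean train R2 %.3f\n",
              nrow(x$beta), ncol(x$beta), mean(x$r2_train)))
  invisible(x)
}
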