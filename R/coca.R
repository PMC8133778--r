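# Constrained Correlation Analysis (CoCA): one neural projection per mouse
# (weights shared across assays) and one behavioral projection per assay
# (weights shared across mice), jointly maximizing the summed Pearson
# correlations of the projections over all sessions.

#' Normalize a behavioral variable matrix
#'
#' All channels are normalized to zero mean and unit variance, except
#' channels named in `minmax` (the EPM's normalized |x| and |y| positions),
#' which are min-max scaled to \[0, 1\] instead.
#'
#' @param Y numeric matrix, variables x timepoints, with rownames.
#' @param minmax character vector of row names to min-max scale.
#' @return the normalized matrix.
#' @export
normalize_behavior_matrix <- function(Y, minmax = character()) {
  stopifnot(is.matrix(Y), !is.null(rownames(Y)))
  for (nm in rownames(Y)) {
    v <- Y[nm, ]
    if (nm %in% minmax) {
      rng <- range(v)
      if (diff(rng) == 0) stop("behavioral channel '", nm, "' is constant")
      Y[nm, ] <- (v - rng[1]) / diff(rng)
    } else {
      s <- stats::sd(v)
      if (s == 0) stop("behavioral channel '", nm, "' is constant")
      Y[nm, ] <- (v - mean(v)) / s
    }
  }
  Y
}

#' Assemble a CoCA dataset
#'
#' @param sessions list of sessions, each a list with `mouse` (id), `assay`
#'   (id), `X` (cells x timepoints, co-registered cell order shared across
#'   the mouse's assays), `Y` (behavioral variables x timepoints,
#'   normalized), and `split` (factor from [make_interleaved_split()]).
#' @return list of class `coca_dataset`.
#' @export
coca_dataset <- function(sessions) {
  stopifnot(length(sessions) >= 1)
  for (s in sessions) {
    stopifnot(is.matrix(s$X), is.matrix(s$Y), ncol(s$X) == ncol(s$Y),
              length(s$split) == ncol(s$X))
    if (!any(s$split == "train")) stop("empty training mask in a session")
  }
  for (m in unique(vapply(sessions, `[[`, "", "mouse"))) {
    ks <- vapply(Filter(function(s) s$mouse == m, sessions), function(s) nrow(s$X), 1L)
    if (length(unique(ks)) != 1)
      stop("mouse ", m, ": cell count differs across assays (co-registration broken)")
  }
  for (a in unique(vapply(sessions, `[[`, "", "assay"))) {
    ps <- vapply(Filter(function(s) s$assay == a, sessions), function(s) nrow(s$Y), 1L)
    if (length(unique(ps)) != 1)
      stop("assay ", a, ": behavioral variable count differs across mice")
  }
  structure(sessions, class = "coca_dataset")
}

# Pearson correlation of projections and its gradients w.r.t. the weight
# vectors. X: k x T, Y: p x T, n: k, b: p. The gradient of r w.r.t. the
# projection is already centered, so the centering projector is implicit.
#' @noRd
coca_corr_grad <- function(X, Y, n, b) {
  u <- as.numeric(crossprod(n, X))
  v <- as.numeric(crossprod(b, Y))
  uc <- u - mean(u); vc <- v - mean(v)
  su <- sqrt(sum(uc^2)); sv <- sqrt(sum(vc^2))
  if (su == 0 || sv == 0)
    return(list(r = 0, gn = numeric(length(n)), gb = numeric(length(b))))
  r <- sum(uc * vc) / (su * sv)
  drdu <- vc / (su * sv) - r * uc / su^2
  drdv <- uc / (su * sv) - r * vc / sv^2
  list(r = r, gn = as.numeric(X %*% drdu), gb = as.numeric(Y %*% drdv))
}

#' Fit CoCA by Adam gradient ascent
#'
#' Maximizes sum over mice i and assays j of corr(n_i' X_ij, b_j' Y_ij) on
#' the training timepoints, with the neural weights n_i shared across
#' assays within a mouse and the behavioral weights b_j shared across mice
#' within an assay. Weights start from seeded random-normal vectors; the
#' best of `restarts` runs by final objective is kept. Convergence is a
#' relative objective change below `tol` over `tol_window` iterations (or
#' `max_iter`). Correlation is scale-invariant, so reported weights are
#' unit-norm, with signs flipped so training correlations are non-negative
#' where jointly possible.
#'
#' @param dataset a [coca_dataset()].
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param max_iter,tol,tol_window convergence control.
#' @param restarts random restarts.
#' @param seed RNG seed.
#' @return list of class `coca_fit`: `n` (named list per mouse), `b` (per
#'   assay), `objective_trace`, `correlations` (per-session train/test r).
#' @export
fit_coca <- function(dataset, lr = 0.01, beta1 = 0.9, beta2 = 0.999,
                     max_iter = 10000, tol = 1e-7, tol_window = 50,
                     restarts = 5, seed = 1) {
  stopifnot(inherits(dataset, "coca_dataset"))
  mice <- unique(vapply(dataset, `[[`, "", "mouse"))
  assays <- unique(vapply(dataset, `[[`, "", "assay"))
  k <- vapply(mice, function(m)
    nrow(Filter(function(s) s$mouse == m, dataset)[[1]]$X), 1L)
  p <- vapply(assays, function(a)
    nrow(Filter(function(s) s$assay == a, dataset)[[1]]$Y), 1L)
  tr <- lapply(dataset, function(s) {
    idx <- which(s$split == "train")
    list(X = s$X[, idx, drop = FALSE], Y = s$Y[, idx, drop = FALSE],
         mouse = s$mouse, assay = s$assay)
  })

  run_once <- function(run_seed) {
    n_w <- with_seed(run_seed, lapply(stats::setNames(k, mice), stats::rnorm))
    b_w <- with_seed(run_seed + 1L, lapply(stats::setNames(p, assays), stats::rnorm))
    m1 <- list(n = lapply(n_w, function(x) 0 * x), b = lapply(b_w, function(x) 0 * x))
    m2 <- m1
    obj_trace <- numeric()
    for (it in seq_len(max_iter)) {
      gn <- lapply(n_w, function(x) 0 * x)
      gb <- lapply(b_w, function(x) 0 * x)
      obj <- 0
      for (s in tr) {
        cg <- coca_corr_grad(s$X, s$Y, n_w[[s$mouse]], b_w[[s$assay]])
        obj <- obj + cg$r
        gn[[s$mouse]] <- gn[[s$mouse]] + cg$gn
        gb[[s$assay]] <- gb[[s$assay]] + cg$gb
      }
      if (!is.finite(obj)) stop("CoCA objective diverged (non-finite)")
      obj_trace[it] <- obj
      # Adam ascent step, bias-corrected
      upd <- function(w, g, m1v, m2v) {
        m1v <- beta1 * m1v + (1 - beta1) * g
        m2v <- beta2 * m2v + (1 - beta2) * g^2
        w <- w + lr * (m1v / (1 - beta1^it)) /
          (sqrt(m2v / (1 - beta2^it)) + 1e-8)
        list(w, m1v, m2v)
      }
      for (m in mice) {
        u <- upd(n_w[[m]], gn[[m]], m1$n[[m]], m2$n[[m]])
        n_w[[m]] <- u[[1]]; m1$n[[m]] <- u[[2]]; m2$n[[m]] <- u[[3]]
      }
      for (a in assays) {
        u <- upd(b_w[[a]], gb[[a]], m1$b[[a]], m2$b[[a]])
        b_w[[a]] <- u[[1]]; m1$b[[a]] <- u[[2]]; m2$b[[a]] <- u[[3]]
      }
      if (it > tol_window) {
        prev <- obj_trace[it - tol_window]
        if (abs(obj_trace[it] - prev) < tol * max(1, abs(prev))) break
      }
    }
    list(n = n_w, b = b_w, objective = obj_trace[length(obj_trace)],
         trace = obj_trace)
  }

  runs <- lapply(seq_len(restarts), function(r) run_once(seed + 131L * r))
  best <- runs[[which.max(vapply(runs, `[[`, 0, "objective"))]]
  n_w <- lapply(best$n, function(x) x / sqrt(sum(x^2)))
  b_w <- lapply(best$b, function(x) x / sqrt(sum(x^2)))
  # sign convention: flip so summed training correlations are non-negative
  for (m in mice) {
    rs <- vapply(tr[vapply(tr, function(s) s$mouse == m, TRUE)], function(s)
      coca_corr_grad(s$X, s$Y, n_w[[m]], b_w[[s$assay]])$r, 0)
    if (sum(rs) < 0) n_w[[m]] <- -n_w[[m]]
  }
  for (a in assays) {
    rs <- vapply(tr[vapply(tr, function(s) s$assay == a, TRUE)], function(s)
      coca_corr_grad(s$X, s$Y, n_w[[s$mouse]], b_w[[a]])$r, 0)
    if (sum(rs) < 0) b_w[[a]] <- -b_w[[a]]
  }
  cors <- do.call(rbind, lapply(dataset, function(s) {
    proj_r <- function(idx) {
      if (!any(idx)) return(NA_real_)
      stats::cor(as.numeric(crossprod(n_w[[s$mouse]], s$X[, idx, drop = FALSE])),
                 as.numeric(crossprod(b_w[[s$assay]], s$Y[, idx, drop = FALSE])))
    }
    data.frame(mouse = s$mouse, assay = s$assay,
               r_train = proj_r(s$split == "train"),
               r_test = proj_r(s$split == "test"))
  }))
  structure(list(n = n_w, b = b_w, objective_trace = best$trace,
                 objective = best$objective, correlations = cors,
                 # Adam is not a strict ascent method; decreases beyond
                 # tolerance are monitored rather than fatal
                 n_objective_decreases = sum(diff(best$trace) < -1e-6)),
            class = "coca_fit")
}

#' @export
print.coca_fit <- function(x, ...) {
  cat(sprintf("<coca_fit> objective %.4f after %d iterations\n",
              x$objective, length(x$objective_trace)))
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' CoCA significance by random neural projections
#'
#' For each session, the test-set correlation between the fitted behavioral
#' projection and `n_proj` random unit-norm neural projections forms the
#' null; the one-tailed empirical p-value is
#' (1 + #\{null >= observed\}) / (1 + n_proj). A random projection can beat
#' the fitted one, since both are evaluated on withheld data.
#'
#' @param fit a `coca_fit`.
#' @param dataset the [coca_dataset()] it was fit on.
#' @param n_proj random projections per session.
#' @param seed RNG seed.
#' @return data.frame with per-session observed test r, p-value and the
#'   null mean; attribute `null` holds the full null matrix.
#' @export
coca_significance <- function(fit, dataset, n_proj = 1000, seed = 1) {
  stopifnot(inherits(fit, "coca_fit"), inherits(dataset, "coca_dataset"))
  nulls <- matrix(NA_real_, n_proj, length(dataset))
  out <- do.call(rbind, lapply(seq_along(dataset), function(i) {
    s <- dataset[[i]]
    idx <- s$split == "test"
    B <- as.numeric(crossprod(fit$b[[s$assay]], s$Y[, idx, drop = FALSE]))
    obs <- stats::cor(as.numeric(crossprod(fit$n[[s$mouse]],
                                           s$X[, idx, drop = FALSE])), B)
    null_r <- with_seed(seed + i, vapply(seq_len(n_proj), function(j) {
      w <- stats::rnorm(nrow(s$X))
      w <- w / sqrt(sum(w^2))
      stats::cor(as.numeric(crossprod(w, s$X[, idx, drop = FALSE])), B)
    }, numeric(1)))
    nulls[, i] <<- null_r
    data.frame(mouse = s$mouse, assay = s$assay, r_test = obs,
               p = (1 + sum(null_r >= obs)) / (1 + n_proj),
               null_mean = mean(null_r))
  }))
  attr(out, "null") <- nulls
  out
}
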