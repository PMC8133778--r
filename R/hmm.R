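# Gaussian-emission hidden Markov model, diagonal covariance, fit by EM
# (Baum-Welch with per-step scaling) and decoded by Viterbi.

#' @noRd
hmm_log_emissions <- function(obs, means, vars) {
  T_ <- nrow(obs); K <- nrow(means)
  logB <- matrix(0, T_, K)
  for (k in seq_len(K))
    logB[, k] <- rowSums(stats::dnorm(obs, matrix(means[k, ], T_, ncol(obs), byrow = TRUE),
                                      matrix(sqrt(vars[k, ]), T_, ncol(obs), byrow = TRUE),
                                      log = TRUE))
  logB
}

#' Fit a Gaussian HMM by expectation maximization
#'
#' Diagonal-covariance Gaussian emissions; scaled forward-backward
#' recursions; the log-likelihood is non-decreasing across iterations (an
#' EM guarantee, asserted in tests). Non-convergence after `max_iter`
#' keeps the best parameters with a warning.
#'
#' @param obs numeric matrix, timepoints x dimensions.
#' @param n_states number of hidden states.
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @param seed seed for the initial state means (drawn from the data).
#' @return list: `pi0`, `transmat`, `means`, `vars`, `loglik_trace`,
#'   `gamma` (posterior state probabilities), `converged`.
#' @export
gaussian_hmm_em <- function(obs, n_states, max_iter = 500, tol = 1e-6, seed = 1) {
  obs <- as.matrix(obs)
  T_ <- nrow(obs); d <- ncol(obs); K <- n_states
  if (nrow(unique(obs)) < K) stop("need at least n_states distinct observations")
  means <- with_seed(seed, obs[sample.int(T_, K), , drop = FALSE])
  vars <- matrix(apply(obs, 2, stats::var), K, d, byrow = TRUE)
  vars[vars <= 0] <- 1e-6
  pi0 <- rep(1 / K, K)
  A <- matrix(0.2 / max(K - 1, 1), K, K); diag(A) <- if (K > 1) 0.8 else 1
  loglik_trace <- numeric()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logB <- hmm_log_emissions(obs, means, vars)
    off <- apply(logB, 1, max)
    B <- exp(logB - off)
    # scaled forward
    alpha <- matrix(0, T_, K)
    cvec <- numeric(T_)
    a <- pi0 * B[1, ]
    cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
    for (t in 2:T_) {
      a <- as.numeric(crossprod(A, alpha[t - 1, ])) * B[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
    ll <- sum(log(cvec)) + sum(off)
    loglik_trace[it] <- ll
    # scaled backward
    beta <- matrix(0, T_, K)
    beta[T_, ] <- 1
    for (t in (T_ - 1):1)
      beta[t, ] <- as.numeric(A %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    # transition expectations
    xi_sum <- matrix(0, K, K)
    for (t in seq_len(T_ - 1)) {
      xi <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * A / cvec[t + 1]
      xi_sum <- xi_sum + xi
    }
    # M step
    pi0 <- gamma[1, ]
    A <- xi_sum / pmax(rowSums(xi_sum), .Machine$double.eps)
    w <- colSums(gamma)
    means <- crossprod(gamma, obs) / w
    for (k in seq_len(K)) {
      dev <- sweep(obs, 2, means[k, ])
      vars[k, ] <- colSums(gamma[, k] * dev^2) / w[k]
    }
    vars[vars < 1e-6] <- 1e-6
    if (it > 1 && abs(ll - loglik_trace[it - 1]) <
        tol * max(1, abs(loglik_trace[it - 1]))) { converged <- TRUE; break }
  }
  if (!converged) warning("HMM EM did not converge in ", max_iter,
                          " iterations; keeping the last parameters")
  logB <- hmm_log_emissions(obs, means, vars)
  list(pi0 = pi0, transmat = A, means = means, vars = vars,
       loglik_trace = loglik_trace, gamma = gamma, converged = converged,
       logB = logB)
}

#' Viterbi decoding of a fitted Gaussian HMM
#'
#' @param fit output of [gaussian_hmm_em()].
#' @param obs the observation matrix the model was fit to (or compatible).
#' @return integer vector of most-likely states, one per timepoint.
#' @export
hmm_viterbi <- function(fit, obs) {
  logB <- hmm_log_emissions(as.matrix(obs), fit$means, fit$vars)
  T_ <- nrow(logB); K <- ncol(logB)
  logA <- log(pmax(fit$transmat, .Machine$double.xmin))
  delta <- matrix(-Inf, T_, K)
  psi <- matrix(0L, T_, K)
  delta[1, ] <- log(pmax(fit$pi0, .Machine$double.xmin)) + logB[1, ]
  for (t in 2:T_) {
    for (k in seq_len(K)) {
      cand <- delta[t - 1, ] + logA[, k]
      psi[t, k] <- which.max(cand)
      delta[t, k] <- cand[psi[t, k]] + logB[t, k]
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(delta[T_, ])
  for (t in (T_ - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}
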