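# Decoding: interleaved splits, linear SVM arm-type classification with
# permutation significance, linear regression of the EPM location index.

#' Interleaved train/test split
#'
#' Alternating 60 s training and 60 s testing segments with 10 s excluded
#' gaps between data types: \[train, gap, test, gap, train, ...\]. The gaps
#' keep slow calcium dynamics from leaking activity between the sets.
#'
#' @param n_timepoints number of neural samples.
#' @param fs sampling rate, Hz.
#' @param block_s,gap_s segment and gap lengths, seconds.
#' @return factor of length `n_timepoints` with levels train/excluded/test.
#' @export
make_interleaved_split <- function(n_timepoints, fs, block_s = 60, gap_s = 10) {
  if (n_timepoints / fs < block_s + gap_s)
    stop("session shorter than one training segment plus gap")
  unit <- c(rep("train", round(block_s * fs)), rep("excluded", round(gap_s * fs)),
            rep("test", round(block_s * fs)), rep("excluded", round(gap_s * fs)))
  roles <- rep(unit, length.out = n_timepoints)
  factor(roles, levels = c("train", "excluded", "test"))
}

# Matthews correlation coefficient from binary vectors.
#' @noRd
mcc <- function(truth, pred) {
  tp <- sum(truth & pred); tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Decode arm type with a linear SVM
#'
#' Fits a linear max-margin classifier with balanced class weights on the
#' training timepoints (center samples excluded from training and testing:
#' they carry no arm label) and reports the Matthews correlation
#' coefficient (MCC) on the withheld test timepoints. Significance comes
#' from refitting with shuffled training labels (`n_perm` trials);
#' p = (1 + #\{null >= observed\}) / (1 + n_perm).
#'
#' @param traces a z-scored [trace_matrix()].
#' @param zones per-sample zone labels.
#' @param split factor from [make_interleaved_split()].
#' @param cost SVM regularization constant C.
#' @param n_perm label permutations for the null distribution.
#' @param seed RNG seed for the permutations.
#' @return list of class `decoder_result`: `mcc`, `p_perm`, `null_mcc`,
#'   `decision_values` (per included test timepoint), `pred`, `truth_labels`.
#' @export
decode_arm_type <- function(traces, zones, split, cost = 1, n_perm = 100,
                            seed = 1) {
  stopifnot(length(zones) == ncol(traces$values), length(split) == length(zones))
  lab <- ifelse(zones %in% c("open1", "open2"), "open",
                ifelse(zones %in% c("closed1", "closed2"), "closed", NA))
  tr_i <- which(split == "train" & !is.na(lab))
  te_i <- which(split == "test" & !is.na(lab))
  if (length(unique(lab[tr_i])) < 2) stop("training set contains a single class")
  if (length(unique(lab[te_i])) < 2) stop("test set contains a single class")
  x_tr <- t(traces$values[, tr_i, drop = FALSE])
  x_te <- t(traces$values[, te_i, drop = FALSE])
  y_tr <- factor(lab[tr_i], levels = c("closed", "open"))
  y_te <- factor(lab[te_i], levels = c("closed", "open"))
  bal <- function(y) {
    tab <- table(y)
    w <- length(y) / (length(tab) * tab)
    stats::setNames(as.numeric(w), names(tab))
  }
  fit_eval <- function(y) {
    m <- e1071::svm(x_tr, y, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = bal(y))
    pr <- stats::predict(m, x_te, decision.values = TRUE)
    list(mcc = mcc(y_te == "open", pr == "open"),
         decision = as.numeric(attr(pr, "decision.values")), pred = pr)
  }
  obs <- fit_eval(y_tr)
  null_mcc <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    fit_eval(sample(y_tr))$mcc, numeric(1)))
  structure(list(mcc = obs$mcc, p_perm = (1 + sum(null_mcc >= obs$mcc)) / (1 + n_perm),
                 null_mcc = null_mcc, decision_values = obs$decision,
                 pred = obs$pred, truth_labels = y_te, test_idx = te_i),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  if (!is.null(x$mcc))
    cat(sprintf("<decoder_result> test MCC %.3f (permutation p = %.3g, %d trials)\n",
                x$mcc, x$p_perm, length(x$null_mcc)))
  if (!is.null(x$r_test))
    cat(sprintf("<decoder_result> test r %.3f (predictions clipped to [-1, 1])\n",
                x$r_test))
  invisible(x)
}

#' Predict the EPM location index from population activity
#'
#' Ordinary least squares on the training timepoints; predictions are
#' clipped to \[-1, 1\] before evaluation and the Pearson correlation on
#' the withheld test timepoints is reported. Rank-deficient designs fall
#' back to a small ridge penalty with a warning.
#'
#' @param traces a z-scored [trace_matrix()].
#' @param index per-sample location index.
#' @param split factor from [make_interleaved_split()].
#' @return list of class `decoder_result`: `r_test`, `pred_test` (clipped),
#'   `coefficients`.
#' @export
predict_location_index <- function(traces, index, split) {
  stopifnot(length(index) == ncol(traces$values), length(split) == length(index))
  tr_i <- which(split == "train")
  te_i <- which(split == "test")
  x_tr <- cbind(1, t(traces$values[, tr_i, drop = FALSE]))
  x_te <- cbind(1, t(traces$values[, te_i, drop = FALSE]))
  qr_x <- qr(x_tr)
  if (qr_x$rank < ncol(x_tr)) {
    warning("rank-deficient design; using a small ridge penalty")
    xtx <- crossprod(x_tr)
    beta <- solve(xtx + diag(1e-6 * mean(diag(xtx)), ncol(x_tr)),
                  crossprod(x_tr, index[tr_i]))
  } else {
    beta <- qr.coef(qr_x, index[tr_i])
  }
  pred <- clip(as.numeric(x_te %*% beta), -1, 1)
  structure(list(r_test = stats::cor(pred, index[te_i]), pred_test = pred,
                 coefficients = as.numeric(beta), test_idx = te_i),
            class = "decoder_result")
}
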