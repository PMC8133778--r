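# Small internal helpers shared across modules.

#' @noRd
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Centered moving average with edge shrinkage (window truncated at the ends).
# half-window: floor(w/2) before, remainder after, matching an almost-centered
# window of w samples.
#' @noRd
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - floor(w / 2), 1L)
  hi <- pmin(seq_len(n) + ceiling(w / 2) - 1L, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Maximal runs of TRUE; returns data.frame(start, end) in frame indices.
#' @noRd
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Evaluate a function with a temporary RNG state so callers' streams are
# untouched; `seed` fully determines the result.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Frame index covering time t (seconds), frames are [(i-1)/fps, i/fps).
#' @noRd
time_to_frame <- function(t, fps) pmin(pmax(floor(t * fps) + 1L, 1L), .Machine$integer.max)
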