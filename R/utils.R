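#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Centered boxcar mean (edges use the available shorter window).
#' @noRd
boxcar_smooth <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Peak of a lightly smoothed signal; the 0.5 s boxcar suppresses the
#' upward bias of the raw max statistic under measurement noise while
#' leaving flat contraction plateaus untouched.
#' @noRd
smoothed_peak <- function(x, fs, smooth_s = 0.5) {
  max(boxcar_smooth(x, max(1L, round(smooth_s * fs))))
}

#' Sliding lower-envelope: per-window low quantile of the tension signal.
#' Spontaneous bumps and EFS spikes occupy a minority of each window, so a
#' low quantile tracks basal tension underneath them.
#' @noRd
lower_envelope <- function(x, fs, window_s = 30, step_s = 5, prob = 0.1) {
  n <- length(x)
  w <- max(2L, round(window_s * fs))
  if (w > n) stop("segment shorter than the envelope window", call. = FALSE)
  step <- max(1L, round(step_s * fs))
  starts <- seq(1L, n - w + 1L, by = step)
  env <- vapply(starts, function(s) {
    stats::quantile(x[s:(s + w - 1L)], prob, names = FALSE, type = 7)
  }, numeric(1))
  list(t = (starts - 1L + w / 2) / fs, env = env, window_s = w / fs)
}

# Deterministic child-seed derivation; keeps results below 2^31 - 1 so the
# value is a valid R integer seed.
child_seed <- function(master_seed, k) {
  as.integer(((as.numeric(master_seed) %% 1e6) * 2039 + 9973 * as.numeric(k)) %%
               2147483647)
}

# Half-open interval overlap test for [a1, a2) vs [b1, b2)
intervals_overlap <- function(a1, a2, b1, b2) a1 < b2 & b1 < a2

#' Subtract a set of closed exclusion intervals from [lo, hi]; returns a
#' matrix with columns start, end of the remaining sub-intervals.
#' @noRd
interval_complement <- function(lo, hi, exclude) {
  if (is.null(exclude) || nrow(exclude) == 0) {
    return(matrix(c(lo, hi), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  ex <- exclude[order(exclude[, 1]), , drop = FALSE]
  out <- NULL
  cur <- lo
  for (i in seq_len(nrow(ex))) {
    s <- max(ex[i, 1], lo); e <- min(ex[i, 2], hi)
    if (e <= cur) next
    if (s > cur) out <- rbind(out, c(cur, min(s, hi)))
    cur <- max(cur, e)
    if (cur >= hi) break
  }
  if (cur < hi) out <- rbind(out, c(cur, hi))
  if (is.null(out)) out <- matrix(numeric(0), ncol = 2)
  colnames(out) <- c("start", "end")
  out
}
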