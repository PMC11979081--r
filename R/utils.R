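# Internal helpers shared across modules.

# Trapezoidal integral of y over x (thin wrapper so the integration rule is
# defined in exactly one place).
trapz_area <- function(x, y) {
  pracma::trapz(x, y)
}

# Draw from N(mean, sd) restricted to the symmetric window (lo, 2*mean - lo).
# Two-sided symmetric truncation leaves the mean of the draw equal to `mean`,
# unlike one-sided clipping, so configured group means are preserved exactly.
rnorm_sym_trunc <- function(n, mean, sd, lo) {
  hi <- 2 * mean - lo
  if (!(lo < mean && mean < hi)) {
    abort("`lo` must be below `mean` for symmetric truncation.")
  }
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lo | out >= hi)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lo | out[bad] >= hi]
    guard <- guard + 1L
  }
  if (length(bad) > 0L) out[bad] <- mean
  out
}

# Local maxima of x (strictly greater than the left neighbour, not less than
# the right), optionally suppressing peaks closer than `min_dist` samples to a
# taller peak (greedy, tallest first).
find_peaks <- function(x, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (length(idx) == 0L || min_dist <= 1L) return(idx)
  ord <- idx[order(x[idx], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
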