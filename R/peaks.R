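# Local-extremum detection with topographic prominence. The prominence of a
# peak is its height above the higher of the two "saddle" minima separating
# it from taller terrain (or from the signal edge). Written in-house because
# no installed peak finder exposes a prominence filter; the signals here are
# short (minutes at tens of Hz) so the straightforward O(n * n_peaks) scan
# is more than fast enough.

# Returns indices of local maxima of x with prominence >= prom_min, at least
# min_dist samples apart (taller peaks win ties).
find_peaks <- function(x, prom_min = 0, min_dist = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  # strict rise on the left, non-rise on the right: first sample of a flat top
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))

  prom <- vapply(cand, function(i) {
    h <- x[i]
    j <- i - 1L; left_min <- h
    while (j >= 1L && x[j] <= h) { left_min <- min(left_min, x[j]); j <- j - 1L }
    j <- i + 1L; right_min <- h
    while (j <= n && x[j] <= h) { right_min <- min(right_min, x[j]); j <- j + 1L }
    h - max(left_min, right_min)
  }, numeric(1))

  keep <- cand[prom >= prom_min]
  if (length(keep) <= 1L || min_dist <= 1L) return(keep)
  # enforce minimum separation, keeping the tallest of any crowded cluster
  ord <- keep[order(x[keep], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in ord) {
    if (all(abs(i - chosen) >= min_dist)) chosen <- c(chosen, i)
  }
  sort(chosen)
}

# Minima are maxima of the mirrored signal.
find_minima <- function(x, prom_min = 0, min_dist = 1L) {
  find_peaks(-x, prom_min = prom_min, min_dist = min_dist)
}
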