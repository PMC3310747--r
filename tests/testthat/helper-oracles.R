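# Brute-force oracles, written independently of the package internals:
# plain per-peak / per-window loops with no interval arithmetic shared
# with the implementation.

# For each peak, scan every window; removed iff strictly inside one.
oracle_removed_mask <- function(mz, windows) {
  out <- logical(length(mz))
  for (i in seq_along(mz)) {
    for (w in seq_len(nrow(windows))) {
      if (mz[i] > windows$lo[w] && mz[i] < windows$hi[w]) {
        out[i] <- TRUE
        break
      }
    }
  }
  out
}

# O(n^2) sliding-window rank oracle: peak i kept iff fewer than h peaks in
# [mz_i - hw, mz_i + hw] beat it (higher intensity, or equal intensity at
# lower m/z).
oracle_window_keep <- function(mz, int, hw, h) {
  n <- length(mz)
  keep <- logical(n)
  for (i in seq_len(n)) {
    beats <- 0L
    for (j in seq_len(n)) {
      if (abs(mz[j] - mz[i]) <= hw &&
          (int[j] > int[i] || (int[j] == int[i] && mz[j] < mz[i])))
        beats <- beats + 1L
    }
    keep[i] <- beats < h
  }
  keep
}

# Descending-intensity cluster walk: a retained peak discards strictly
# less intense peaks 1 +/- tol or 2 +/- tol Da above it.
oracle_deisotope_keep <- function(mz, int, tol) {
  n <- length(mz)
  removed <- logical(n)
  for (i in order(int, decreasing = TRUE)) {
    if (removed[i]) next
    for (j in seq_len(n)) {
      d <- mz[j] - mz[i]
      if ((abs(d - 1) <= tol || abs(d - 2) <= tol) && int[j] < int[i])
        removed[j] <- TRUE
    }
  }
  !removed
}

# A quick unannotated random spectrum for oracle suites.
random_spectrum <- function(n_peaks = 120, mz_range = c(100, 2000)) {
  etd_spectrum(stats::runif(n_peaks, mz_range[1], mz_range[2]),
               stats::rexp(n_peaks, 1 / 50),
               precursor_mz = stats::runif(1, 300, 900),
               precursor_charge = sample(3:7, 1))
}
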