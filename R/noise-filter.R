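#' Parameters for the two-stage noise filter
#'
#' Stage one removes isotope peaks 1-2 Da above a more intense peak
#' (deisotoping). Stage two retains, around every peak, only the top `h`
#' most intense peaks within a sliding window: +/-27 Da with limit `h1`
#' when searching for 1+ product ions, +/-14 Da with limit `h2` for 2+
#' product ions. `h` should equal the number of ion series searched for:
#' 2 for c and z-dot only, 3 when y ions are also considered.
#'
#' @param h1 Peaks kept per +/-`window_1plus` Da window (1+ products).
#'   Default 2; recommended 3 for c/z-dot/y searches.
#' @param h2 Peaks kept per +/-`window_2plus` Da window (2+ products).
#'   Default 2; recommended 3.
#' @param window_1plus Half-width in Da of the 1+ window. Default 27.
#' @param window_2plus Half-width in Da of the 2+ window. Default 14.
#' @param isotope_tol Tolerance in Da around the +1 and +2 Da isotope
#'   spacings. Default 0.2.
#' @return A list of class `noise_filter_params`.
#' @export
noise_filter_params <- function(h1 = 2, h2 = 2, window_1plus = 27,
                                window_2plus = 14, isotope_tol = 0.2) {
  if (h1 < 1 || h2 < 1) stop("h1 and h2 must be >= 1")
  if (window_1plus <= 0 || window_2plus <= 0) stop("windows must be positive")
  if (isotope_tol < 0) stop("isotope_tol must be non-negative")
  structure(list(h1 = as.integer(h1), h2 = as.integer(h2),
                 window_1plus = window_1plus, window_2plus = window_2plus,
                 isotope_tol = isotope_tol),
            class = "noise_filter_params")
}

#' Remove isotope peaks, keeping each cluster's most intense peak
#'
#' Peaks are visited in order of decreasing intensity (ties: lower m/z
#' first). Each peak that has not itself been removed discards any strictly
#' less intense peak lying 1 +/- tol or 2 +/- tol Da above it. A removed
#' isotope peak cannot shield peaks further up the envelope, because
#' removal always acts relative to a retained peak.
#'
#' @param spectrum An [etd_spectrum()].
#' @param params A [noise_filter_params()] object; only `isotope_tol` is
#'   used here.
#' @return A new `etd_spectrum` without the isotope satellites.
#' @export
deisotope <- function(spectrum, params = noise_filter_params()) {
  stopifnot(inherits(spectrum, "etd_spectrum"),
            inherits(params, "noise_filter_params"))
  mz <- spectrum$mz
  int <- spectrum$intensity
  n <- length(mz)
  if (n <= 1L) return(spectrum)
  tol <- params$isotope_tol
  removed <- logical(n)
  for (i in order(-int, mz)) {
    if (removed[i]) next
    d <- mz - mz[i]
    hit <- (abs(d - 1) <= tol | abs(d - 2) <= tol) & int < int[i]
    removed[hit] <- TRUE
  }
  subset_peaks(spectrum, !removed)
}

#' Sliding-window intensity-rank filter
#'
#' A peak survives iff it ranks among the top `h` by intensity within the
#' window centred on it, `[mz - half_width, mz + half_width]`. Every peak
#' gets its own window, so retention does not depend on an arbitrary bin
#' grid. Ties in intensity are broken in favour of the lower m/z peak.
#'
#' @param spectrum An [etd_spectrum()].
#' @param half_width Window half-width in Da.
#' @param h Maximum number of peaks retained per window.
#' @return Logical mask over the spectrum's peaks, `TRUE` for retained.
#' @seealso [apply_noise_filter()] which composes deisotoping with this
#'   filter for both product-ion charges.
#' @export
window_filter <- function(spectrum, half_width, h) {
  stopifnot(inherits(spectrum, "etd_spectrum"))
  if (h < 1) stop("`h` must be >= 1")
  if (half_width <= 0) stop("`half_width` must be positive")
  mz <- spectrum$mz
  int <- spectrum$intensity
  n <- length(mz)
  if (n == 0L) return(logical(0))
  # peaks sorted by mz: the window around peak i is a contiguous run
  lo <- findInterval(mz - half_width, mz, left.open = TRUE) + 1L
  hi <- findInterval(mz + half_width, mz)
  keep <- logical(n)
  for (i in seq_len(n)) {
    j <- lo[i]:hi[i]
    beats <- int[j] > int[i] | (int[j] == int[i] & mz[j] < mz[i])
    keep[i] <- sum(beats) < h
  }
  keep
}

#' Two-stage noise filtering for 1+ and 2+ product-ion searches
#'
#' Deisotopes the spectrum, then produces two filtered views: the top `h1`
#' peaks per +/-`window_1plus` Da window (for matching 1+ product ions) and
#' the top `h2` peaks per +/-`window_2plus` Da window (for 2+ product
#' ions). The input spectrum is not modified.
#'
#' @param spectrum An [etd_spectrum()].
#' @param params A [noise_filter_params()] object.
#' @return A list with elements `singly` and `doubly`, each an
#'   `etd_spectrum`, plus `deisotoped` (the intermediate spectrum).
#' @export
apply_noise_filter <- function(spectrum, params = noise_filter_params()) {
  stopifnot(inherits(spectrum, "etd_spectrum"),
            inherits(params, "noise_filter_params"))
  d <- deisotope(spectrum, params)
  list(
    singly = subset_peaks(d, window_filter(d, params$window_1plus, params$h1)),
    doubly = subset_peaks(d, window_filter(d, params$window_2plus, params$h2)),
    deisotoped = d)
}
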