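#' Monoisotopic proton mass in Da
#'
#' Used throughout for converting between neutral peptide mass and m/z.
#' Several printed worked examples in the field round the proton to exactly
#' 1 Da; functions that take a `proton` argument accept that simplification.
#'
#' @export
PROTON_MASS <- 1.007276466

#' m/z of a peptide of neutral mass M carrying z protons
#'
#' Computes MH(z+) = (M + z*H)/z, the mass-to-charge ratio of the intact
#' (or charge-reduced) peptide ion. In ETD spectra the charge-reduced
#' precursor series of a parent ion of charge n appears at MH(z+) for
#' z = 1..n.
#'
#' @param M Neutral monoisotopic peptide mass in Da. Must be positive.
#' @param z Charge (number of protons), a positive integer. Vectorised.
#' @param proton Proton mass in Da. Default [PROTON_MASS]; pass `1` to
#'   reproduce back-of-the-envelope examples that round the proton to 1 Da.
#' @return m/z values in Thomson, same length as `z`.
#' @examples
#' mh(1473.58, 1) # ~1474.6, the MH(1+) charge-reduced precursor
#' mh(1473.58, 2) # ~737.8
#' @seealso [neutral_mass()], [reduced_precursor_series()]
#' @export
mh <- function(M, z, proton = PROTON_MASS) {
  if (any(!is.finite(M)) || any(M <= 0))
    stop("neutral mass `M` must be positive and finite")
  if (any(z < 1) || any(z != round(z)))
    stop("charge `z` must be a positive integer")
  (M + z * proton) / z
}

#' Neutral mass implied by an observed precursor m/z and a charge hypothesis
#'
#' Inverse of [mh()]: M = z * precursor_mz - z * H. Round-trips with
#' [mh()] to machine precision.
#'
#' @param precursor_mz Observed precursor m/z in Thomson. Must exceed the
#'   proton mass.
#' @param z Hypothesised charge, a positive integer.
#' @inheritParams mh
#' @return Neutral mass in Da.
#' @examples
#' neutral_mass(492.2, 3) # ~1473.58 Da
#' @export
neutral_mass <- function(precursor_mz, z, proton = PROTON_MASS) {
  if (any(z < 1) || any(z != round(z)))
    stop("charge `z` must be a positive integer")
  if (any(precursor_mz <= proton))
    stop("`precursor_mz` must exceed the proton mass")
  z * precursor_mz - z * proton
}

#' Charge-reduced precursor series of a precursor ion
#'
#' For a precursor observed at `precursor_mz` with parent charge `n`, the
#' charge-reduced (non-dissociated) precursor species appear at MH(z+) for
#' z = 1..n, computed from the neutral mass implied by `n`. The z = n
#' element equals the input precursor m/z; m/z is strictly decreasing in z.
#'
#' @param precursor_mz Observed precursor m/z in Thomson.
#' @param n Parent precursor charge, a positive integer.
#' @inheritParams mh
#' @return A data frame with columns `z` (1..n) and `mz`.
#' @examples
#' reduced_precursor_series(492.2, 3)
#' # z = 1..3 at ~1474.6, ~737.8, 492.2 m/z
#' @export
reduced_precursor_series <- function(precursor_mz, n, proton = PROTON_MASS) {
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("parent charge `n` must be a single positive integer")
  M <- neutral_mass(precursor_mz, n, proton = proton)
  z <- seq_len(n)
  data.frame(z = z, mz = mh(M, z, proton = proton))
}

#' Construct an ETD MS/MS spectrum
#'
#' A spectrum is a peak list (m/z, intensity) together with the precursor
#' m/z and, when the instrument reports it, the precursor charge. Peaks are
#' sorted ascending by m/z; peaks with identical m/z are merged by summing
#' their intensities, so downstream interval arithmetic sees a set rather
#' than a multiset.
#'
#' @param mz Numeric vector of peak m/z values (Thomson), all positive.
#' @param intensity Numeric vector of non-negative intensities, same length.
#' @param precursor_mz Precursor m/z in Thomson.
#' @param precursor_charge Positive integer, or `NA` when the charge is not
#'   known (the usual case on low-resolution ion-trap instruments).
#' @param scan_id Opaque identifier carried through filtering and reporting.
#' @return An object of class `etd_spectrum`: a list with elements `mz`,
#'   `intensity`, `precursor_mz`, `precursor_charge`, `scan_id`.
#' @export
etd_spectrum <- function(mz, intensity, precursor_mz,
                         precursor_charge = NA_integer_, scan_id = "") {
  if (length(mz) != length(intensity))
    stop("`mz` and `intensity` must have the same length")
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("all peak m/z values must be positive and finite")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be non-negative and finite")
  if (length(precursor_mz) != 1L || !is.finite(precursor_mz) || precursor_mz <= 0)
    stop("`precursor_mz` must be a single positive number")
  if (!is.na(precursor_charge) &&
      (precursor_charge < 1 || precursor_charge != round(precursor_charge)))
    stop("`precursor_charge` must be a positive integer or NA")
  ord <- order(mz)
  mz <- unname(mz[ord])
  intensity <- unname(intensity[ord])
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, match(mz, mz), sum))
    mz <- unique(mz)
  }
  structure(
    list(mz = mz, intensity = intensity,
         precursor_mz = as.numeric(precursor_mz),
         precursor_charge = if (is.na(precursor_charge)) NA_integer_
                            else as.integer(precursor_charge),
         scan_id = as.character(scan_id)),
    class = "etd_spectrum")
}

# Rebuild a spectrum from an already sorted, deduplicated peak subset,
# keeping precursor metadata. Internal fast path used by the filters.
subset_peaks <- function(x, keep) {
  structure(
    list(mz = x$mz[keep], intensity = x$intensity[keep],
         precursor_mz = x$precursor_mz,
         precursor_charge = x$precursor_charge,
         scan_id = x$scan_id),
    class = "etd_spectrum")
}

#' Total ion current of a spectrum
#'
#' @param x An `etd_spectrum`.
#' @return Sum of all peak intensities.
#' @export
tic <- function(x) {
  stopifnot(inherits(x, "etd_spectrum"))
  sum(x$intensity)
}

#' Number of peaks in a spectrum
#'
#' @param x An `etd_spectrum`.
#' @return Integer peak count.
#' @export
n_peaks <- function(x) {
  stopifnot(inherits(x, "etd_spectrum"))
  length(x$mz)
}

#' @export
print.etd_spectrum <- function(x, ...) {
  chg <- if (is.na(x$precursor_charge)) "unknown"
         else paste0(x$precursor_charge, "+")
  cat(sprintf("ETD MS/MS spectrum '%s': %d peaks, precursor %.4f m/z (charge %s)\n",
              x$scan_id, length(x$mz), x$precursor_mz, chg))
  if (length(x$mz)) {
    cat(sprintf("  m/z range %.2f-%.2f, TIC %.3g\n",
                min(x$mz), max(x$mz), sum(x$intensity)))
  }
  invisible(x)
}

#' Peak list of a spectrum as a data frame
#'
#' @param x An `etd_spectrum`.
#' @return Data frame with columns `mz` and `intensity`, sorted by m/z.
#' @export
peaks <- function(x) {
  stopifnot(inherits(x, "etd_spectrum"))
  data.frame(mz = x$mz, intensity = x$intensity)
}
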