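#' Parameters for charge-reduced precursor removal
#'
#' The precursor filter removes the intense charge-reduced precursor peaks
#' and their neutral-loss regions from an ETD spectrum before sequence
#' library searching. The removal windows are asymmetric around each
#' MH(z+): the upstream (higher m/z) extent M/(W*z) grows with peptide
#' mass, covering the isotopic envelope; the downstream (lower m/z) extent
#' N1/z (z <= 2) or N2/z (z >= 3) covers the neutral losses.
#'
#' @param W Dimensionless divisor of the mass-proportional upstream window.
#'   Default 500.
#' @param N1 Downstream neutral-loss extent in Da for z = 1 and 2. Default
#'   60, a blanket covering ammonia (-17), water (-18), CO (-28) and
#'   guanidino (-43) losses.
#' @param N2 Downstream extent in Da for z >= 3. Default 18 (water).
#' @param variant `"omssa"` for the mass-proportional filter, `"good"` for
#'   the fixed +/-3.1 Da comparison filter, `"none"` for a passthrough.
#' @return A list of class `precursor_filter_params`.
#' @seealso [apply_precursor_filter()]
#' @export
precursor_filter_params <- function(W = 500, N1 = 60, N2 = 18,
                                    variant = c("omssa", "good", "none")) {
  variant <- match.arg(variant)
  if (W <= 0 || N1 <= 0 || N2 <= 0) stop("W, N1 and N2 must be positive")
  if (N1 < N2) stop("N1 must be >= N2")
  structure(list(W = W, N1 = N1, N2 = N2, variant = variant),
            class = "precursor_filter_params")
}

#' Removal windows of the mass-proportional precursor filter
#'
#' One half-open window per charge-reduced species z = 1..n:
#' (MH(z+) - N1/z, MH(z+) + M/(W*z)) for z = 1, 2 and
#' (MH(z+) - N2/z, MH(z+) + M/(W*z)) for z = 3..n. Peaks strictly inside a
#' window are removed; boundary peaks survive.
#'
#' @param M Neutral peptide mass in Da.
#' @param n Parent precursor charge.
#' @param params A [precursor_filter_params()] object.
#' @inheritParams mh
#' @return Data frame with columns `z`, `lo`, `hi`, sorted by `lo`.
#' @export
omssa_removal_windows <- function(M, n, params = precursor_filter_params(),
                                  proton = PROTON_MASS) {
  stopifnot(inherits(params, "precursor_filter_params"))
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("parent charge `n` must be a single positive integer")
  z <- seq_len(n)
  center <- mh(M, z, proton = proton)
  down <- ifelse(z <= 2, params$N1, params$N2) / z
  up <- M / (params$W * z)
  out <- data.frame(z = z, lo = center - down, hi = center + up)
  out[order(out$lo), , drop = FALSE]
}

#' Removal windows of the fixed-width comparison filter
#'
#' Per charge-reduced species z = 1..n, two windows: a fixed
#' (MH(z+) - 3.1, MH(z+) + 3.1) band around the precursor and a
#' neutral-loss band (MH(z+) - N1/z, MH(z+)).
#'
#' @inheritParams omssa_removal_windows
#' @return Data frame with columns `z`, `lo`, `hi`, sorted by `lo`; two
#'   rows per z.
#' @export
good_removal_windows <- function(M, n, params = precursor_filter_params(),
                                 proton = PROTON_MASS) {
  stopifnot(inherits(params, "precursor_filter_params"))
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("parent charge `n` must be a single positive integer")
  z <- seq_len(n)
  center <- mh(M, z, proton = proton)
  out <- rbind(
    data.frame(z = z, lo = center - 3.1, hi = center + 3.1),
    data.frame(z = z, lo = center - params$N1 / z, hi = center))
  out[order(out$lo), , drop = FALSE]
}

#' Remove charge-reduced precursor and neutral-loss peaks from a spectrum
#'
#' Applies the removal windows of the selected filter variant for the
#' charge-reduced series z = 1..n. A peak is removed iff it lies strictly
#' inside at least one window; peaks exactly on a window boundary are
#' retained. The input spectrum is not modified. Filtering is idempotent.
#'
#' @param spectrum An [etd_spectrum()] with `precursor_mz` set.
#' @param n Parent precursor charge to filter under. Defaults to the
#'   spectrum's own `precursor_charge`. When the charge determination step
#'   yields a candidate set, pass the largest candidate: its windows cover
#'   the shared charge-reduced species of the smaller hypotheses, and
#'   conservative removal is the point of the filter.
#' @param params A [precursor_filter_params()] object selecting the variant.
#' @inheritParams mh
#' @return A new `etd_spectrum` containing the surviving peaks.
#' @examples
#' sp <- etd_spectrum(c(200, 737.8, 900), c(5, 100, 7), precursor_mz = 492.2,
#'                    precursor_charge = 3)
#' apply_precursor_filter(sp) # the 737.8 MH(2+) peak is removed
#' @export
apply_precursor_filter <- function(spectrum, n = spectrum$precursor_charge,
                                   params = precursor_filter_params(),
                                   proton = PROTON_MASS) {
  stopifnot(inherits(spectrum, "etd_spectrum"),
            inherits(params, "precursor_filter_params"))
  if (params$variant == "none") return(spectrum)
  if (is.na(n))
    stop("precursor charge is unknown: run charge determination first, ",
         "or pass the maximum of the search range as `n`")
  M <- neutral_mass(spectrum$precursor_mz, n, proton = proton)
  win <- switch(params$variant,
                omssa = omssa_removal_windows(M, n, params, proton = proton),
                good  = good_removal_windows(M, n, params, proton = proton))
  keep <- !in_any_window(spectrum$mz, win)
  subset_peaks(spectrum, keep)
}

# TRUE for m/z values strictly inside at least one (lo, hi) window.
in_any_window <- function(mz, windows) {
  inside <- rep(FALSE, length(mz))
  for (i in seq_len(nrow(windows))) {
    inside <- inside | (mz > windows$lo[i] & mz < windows$hi[i])
  }
  inside
}
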