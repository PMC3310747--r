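# Monoisotopic residue masses of the 20 standard amino acids (Da) and the
# mass of water; used only to give synthetic fragment ladders realistic
# spacings. The classifier never sees sequence identity.
RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
WATER_MASS <- 18.010565
PHOSPHO_MASS <- 79.96633

#' Parameters of the synthetic ETD spectrum generator
#'
#' The generator emulates the phenomenology of ion-trap ETD spectra of
#' multiply charged (phospho)peptides: a ladder of intense charge-reduced
#' precursor (CP) peaks at MH(z+) for z = 1..n with mass-dependent isotope
#' satellites spaced 1/z Da, water/ammonia neutral-loss (NL) peaks at
#' -o/z Da from each CP peak, incomplete c/z-dot/y fragment ladders from a
#' random residue-mass walk, and uniform low-intensity chemical noise.
#'
#' @param charge_probs Named probability vector over precursor charges.
#'   Default `c("3" = 0.201, "4" = 0.514, "5" = 0.194, "6" = 0.077,
#'   "7" = 0.014)` (renormalised), the charge-state breakdown typical of a
#'   large ion-trap ETD phosphopeptide experiment.
#' @param mass_range Overall neutral-mass range in Da, default 1000-6000.
#'   Within it, mass scales with charge: M is drawn uniformly between
#'   300*n and 850*n Da (clipped to `mass_range`), reflecting that higher
#'   charge states come from longer peptides.
#' @param cp_intensity_scale Median dominance of CP peaks over fragment
#'   peaks. Default 10.
#' @param nl_offsets Neutral-loss offsets in Da applied to every CP peak,
#'   scaled by 1/z on the m/z axis. Default `c(17, 18)` (ammonia, water);
#'   CO (28) and guanidino (43) losses can be added.
#' @param cp_coverage Probability that a given charge-reduced species
#'   z < n is observed at all; the z = n precursor itself is always
#'   present. Default 0.8, emulating variable electron-transfer
#'   efficiency: real ion-trap ETD scans often show only part of the
#'   reduced series, which is what makes charge multiples (3+ vs 6+)
#'   ambiguous on CP evidence alone. Neutral losses are emitted only for
#'   observed species.
#' @param fragment_ion_types Subset of `c("c", "z", "y")` emitted at each
#'   backbone cleavage. Default all three.
#' @param fragment_coverage Probability that a given ion of a given type is
#'   actually observed. Default 0.7.
#' @param noise_peaks Number of uniform chemical-noise peaks. Default 60.
#' @param noise_mean Mean of the exponential noise-intensity law, on the
#'   scale where the median fragment intensity is 100. Default 15.
#' @param mz_jitter Standard deviation in Da of Gaussian m/z measurement
#'   error added to every generated peak. Default 0.1, an ion-trap-like
#'   mass accuracy.
#' @param isotope_envelope Number of isotope satellites per CP peak
#'   (including the monoisotopic peak), or `NULL` (default) for the
#'   mass-dependent rule `min(4, max(1, ceiling(M / 1500)))`.
#' @param phospho_prob Probability that the peptide carries one phospho
#'   group (+79.966 Da folded into the residue walk). Default 0.5.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(charge_probs = c("3" = 0.201, "4" = 0.514,
                                              "5" = 0.194, "6" = 0.077,
                                              "7" = 0.014),
                             mass_range = c(1000, 6000),
                             cp_intensity_scale = 10,
                             nl_offsets = c(17, 18),
                             cp_coverage = 0.8,
                             fragment_ion_types = c("c", "z", "y"),
                             fragment_coverage = 0.7,
                             noise_peaks = 60,
                             noise_mean = 15,
                             mz_jitter = 0.1,
                             isotope_envelope = NULL,
                             phospho_prob = 0.5) {
  if (is.null(names(charge_probs)) || any(charge_probs < 0) ||
      sum(charge_probs) <= 0)
    stop("`charge_probs` must be a named non-negative vector with positive sum")
  if (mz_jitter < 0) stop("`mz_jitter` must be non-negative")
  if (length(mass_range) != 2L || mass_range[1] >= mass_range[2])
    stop("`mass_range` must be an increasing pair")
  fragment_ion_types <- match.arg(fragment_ion_types, c("c", "z", "y"),
                                  several.ok = TRUE)
  structure(list(
    charge_probs = charge_probs / sum(charge_probs),
    mass_range = mass_range,
    cp_intensity_scale = cp_intensity_scale,
    nl_offsets = nl_offsets,
    cp_coverage = cp_coverage,
    fragment_ion_types = fragment_ion_types,
    fragment_coverage = fragment_coverage,
    noise_peaks = as.integer(noise_peaks),
    noise_mean = noise_mean,
    mz_jitter = mz_jitter,
    isotope_envelope = isotope_envelope,
    phospho_prob = phospho_prob),
    class = "generator_params")
}

# Residue-mass walk summing exactly to the target residue mass R. Masses
# are rescaled by a common factor close to 1 so prefix/suffix sums are
# consistent with the precursor mass; sequence realism is not the goal.
residue_walk <- function(R, phospho) {
  target <- R - if (phospho) PHOSPHO_MASS else 0
  n_guess <- max(2L, ceiling(target / 110))
  res <- sample(RESIDUE_MASSES, n_guess + 8, replace = TRUE)
  len <- max(2L, sum(cumsum(res) <= target))
  res <- res[seq_len(len)]
  if (phospho) {
    site <- sample.int(len, 1)
    res[site] <- res[site] + PHOSPHO_MASS
  }
  res * (R / sum(res))
}

#' Generate one annotated synthetic ETD spectrum
#'
#' Draws a precursor charge and neutral mass, then emits the CP ladder
#' with isotope satellites, NL peaks, fragment ions and noise as described
#' in [generator_params()]. Uses the current RNG state; seed control lives
#' in [generate_dataset()].
#'
#' @param params A [generator_params()] object.
#' @param scan_id Identifier for the spectrum.
#' @return A list with elements `spectrum` (an [etd_spectrum()] with the
#'   true charge recorded) and `truth` (list: `scan_id`, `charge`,
#'   `neutral_mass`, `precursor_mz`, and `peaks`, a data frame aligned
#'   with the spectrum's peaks whose `kind` column is one of `"cp"`,
#'   `"nl"`, `"fragment"`, `"noise"`).
#' @export
generate_spectrum <- function(params = generator_params(), scan_id = "synth") {
  stopifnot(inherits(params, "generator_params"))
  n <- as.integer(sample(names(params$charge_probs), 1,
                         prob = params$charge_probs))
  lo <- max(params$mass_range[1], 300 * n)
  hi <- min(params$mass_range[2], 850 * n)
  if (lo >= hi) stop("mass_range infeasible for charge ", n)
  M <- stats::runif(1, lo, hi)
  precursor_mz <- mh(M, n)
  jit <- function(k) stats::rnorm(k, 0, params$mz_jitter)

  n_iso <- if (is.null(params$isotope_envelope))
    min(4L, max(1L, ceiling(M / 1500))) else as.integer(params$isotope_envelope)

  mzs <- numeric(0); ints <- numeric(0); kinds <- character(0)
  add <- function(m, i, k) {
    ok <- m > 50
    mzs <<- c(mzs, m[ok]); ints <<- c(ints, i[ok])
    kinds <<- c(kinds, rep(k, sum(ok)))
  }

  # charge-reduced precursor ladder with 1/z-spaced isotope satellites;
  # species below the parent charge appear with probability cp_coverage
  for (z in seq_len(n)) {
    if (z < n && stats::runif(1) >= params$cp_coverage) next
    base <- stats::rlnorm(1, log(100 * params$cp_intensity_scale), 0.5)
    j <- seq_len(n_iso) - 1L
    add(mh(M, z) + j / z + jit(n_iso), base * 0.65^j, "cp")
    # neutral losses from this reduced precursor, with the same isotope
    # envelope (they are peptide-derived ions like their parent)
    for (o in params$nl_offsets) {
      nl_base <- stats::rlnorm(1, log(40 * params$cp_intensity_scale), 0.5)
      add(mh(M, z) - o / z + j / z + jit(n_iso), nl_base * 0.65^j, "nl")
    }
  }

  # incomplete c / z-dot / y fragment ladders from a residue-mass walk
  res <- residue_walk(M - WATER_MASS, stats::runif(1) < params$phospho_prob)
  pre <- cumsum(res)[-length(res)]
  suf <- (M - WATER_MASS) - pre
  for (ty in params$fragment_ion_types) {
    frag_mass <- switch(ty,
      c = pre + 17.026549,          # c: N-terminal + NH3
      z = suf + 1.991840,           # z-dot: C-terminal + NH - H, radical
      y = suf + WATER_MASS)         # y: C-terminal + H2O
    seen <- stats::runif(length(frag_mass)) < params$fragment_coverage
    k <- sum(seen)
    if (k > 0)
      add(frag_mass[seen] + PROTON_MASS + jit(k),
          stats::rlnorm(k, log(100), 0.7), "fragment")
  }

  # uniform chemical noise
  if (params$noise_peaks > 0) {
    k <- params$noise_peaks
    add(stats::runif(k, 100, mh(M, 1) + 30),
        stats::rexp(k, 1 / params$noise_mean), "noise")
  }

  ord <- order(mzs)
  mzs <- unname(mzs[ord]); ints <- unname(ints[ord]); kinds <- kinds[ord]
  if (anyDuplicated(mzs)) {   # vanishingly rare with jitter; merge anyway
    grp <- match(mzs, mzs)
    ints <- as.numeric(tapply(ints, grp, sum))
    kinds <- kinds[!duplicated(grp)]
    mzs <- unique(mzs)
  }
  sp <- etd_spectrum(mzs, ints, precursor_mz = precursor_mz,
                     precursor_charge = n, scan_id = scan_id)
  list(spectrum = sp,
       truth = list(scan_id = scan_id, charge = n, neutral_mass = M,
                    precursor_mz = precursor_mz,
                    peaks = data.frame(mz = mzs, intensity = ints,
                                       kind = kinds)))
}

#' Generate a reproducible labelled collection of synthetic ETD spectra
#'
#' @param n_spectra Number of spectra to generate.
#' @param params A [generator_params()] object.
#' @param seed Optional integer seed; the same seed reproduces the dataset
#'   exactly.
#' @param mgf Optional path: write the spectra as an MGF file.
#' @param truth_tsv Optional path: write the truth table as TSV.
#' @param keep_annotations Keep per-peak truth annotations for every
#'   spectrum (memory-heavier). Default `FALSE`.
#' @return A list of class `etd_dataset`: `spectra` (list of
#'   [etd_spectrum()]), `truth` (data frame: `scan_id`, `charge`,
#'   `neutral_mass`, `precursor_mz`), optionally `annotations`.
#' @export
generate_dataset <- function(n_spectra, params = generator_params(),
                             seed = NULL, mgf = NULL, truth_tsv = NULL,
                             keep_annotations = FALSE) {
  if (n_spectra < 1) stop("`n_spectra` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_spectra)
  for (i in seq_len(n_spectra)) {
    out[[i]] <- generate_spectrum(params, scan_id = sprintf("synth_%05d", i))
  }
  spectra <- lapply(out, `[[`, "spectrum")
  truth <- data.frame(
    scan_id = vapply(out, function(x) x$truth$scan_id, character(1)),
    charge = vapply(out, function(x) x$truth$charge, integer(1)),
    neutral_mass = vapply(out, function(x) x$truth$neutral_mass, numeric(1)),
    precursor_mz = vapply(out, function(x) x$truth$precursor_mz, numeric(1)))
  ds <- structure(list(spectra = spectra, truth = truth, params = params),
                  class = "etd_dataset")
  if (keep_annotations)
    ds$annotations <- lapply(out, function(x) x$truth$peaks)
  if (!is.null(mgf)) write_mgf(spectra, mgf)
  if (!is.null(truth_tsv))
    utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  ds
}

#' @export
print.etd_dataset <- function(x, ...) {
  cat(sprintf("Synthetic ETD dataset: %d spectra\n", length(x$spectra)))
  print(table(charge = x$truth$charge))
  invisible(x)
}

#' Split a dataset into training and test portions
#'
#' @param dataset An `etd_dataset` from [generate_dataset()].
#' @param n_train Number of spectra (taken in order) for training; the
#'   rest form the test set.
#' @return List with `train` and `test`, each an `etd_dataset`.
#' @export
split_dataset <- function(dataset, n_train) {
  stopifnot(inherits(dataset, "etd_dataset"))
  n <- length(dataset$spectra)
  if (n_train < 1 || n_train >= n)
    stop("`n_train` must be in 1..(n_spectra - 1)")
  idx <- seq_len(n_train)
  take <- function(i) structure(
    list(spectra = dataset$spectra[i],
         truth = dataset$truth[i, , drop = FALSE],
         params = dataset$params),
    class = "etd_dataset")
  list(train = take(idx), test = take(setdiff(seq_len(n), idx)))
}
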