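#' Read a Mascot Generic Format (MGF) peak-list file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. `PEPMASS` (first token) sets the
#' precursor m/z; an optional second token (precursor intensity) is
#' ignored. `CHARGE` sets the precursor charge when present — for
#' multi-charge lists (`CHARGE=3+ and 4+`) the first charge is taken —
#' otherwise the charge is unknown (`NA`). `TITLE` becomes the scan id.
#' Duplicate m/z values within a block are merged by intensity summation.
#'
#' @param path Path to an MGF file.
#' @return A list of [etd_spectrum()] objects. Blocks without a `PEPMASS`
#'   line are skipped with a warning.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begins <- grep("^\\s*BEGIN IONS\\s*$", lines)
  ends <- grep("^\\s*END IONS\\s*$", lines)
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS blocks in ", path)
  spectra <- vector("list", length(begins))
  kept <- logical(length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(trimws(block))]
    is_header <- grepl("^[A-Za-z][A-Za-z0-9_]*=", block)
    headers <- block[is_header]
    key <- toupper(sub("=.*$", "", headers))
    val <- sub("^[^=]*=", "", headers)
    title <- if ("TITLE" %in% key) val[key == "TITLE"][1]
             else paste0("index_", b)
    if (!"PEPMASS" %in% key) {
      warning("MGF block ", b, " (", title, ") has no PEPMASS line; skipped")
      next
    }
    pepmass <- as.numeric(strsplit(trimws(val[key == "PEPMASS"][1]),
                                   "\\s+")[[1]][1])
    charge <- NA_integer_
    if ("CHARGE" %in% key) {
      m <- regmatches(val[key == "CHARGE"][1],
                      regexpr("[0-9]+", val[key == "CHARGE"][1]))
      if (length(m)) charge <- as.integer(m)
    }
    peak_lines <- block[!is_header]
    if (length(peak_lines)) {
      fields <- strsplit(trimws(peak_lines), "[[:space:],]+")
      mz <- as.numeric(vapply(fields, `[`, character(1), 1))
      int <- as.numeric(vapply(fields, `[`, character(1), 2))
      if (anyNA(mz) || anyNA(int))
        stop("malformed peak line in MGF block ", b, " (", title, ")")
    } else {
      mz <- numeric(0); int <- numeric(0)
    }
    spectra[[b]] <- etd_spectrum(mz, int, precursor_mz = pepmass,
                                 precursor_charge = charge, scan_id = title)
    kept[b] <- TRUE
  }
  spectra[kept]
}

#' Write spectra to a Mascot Generic Format (MGF) file
#'
#' Peak values are written to 4 decimal places. When charge assignments
#' are supplied, multi-candidate sets are written in the
#' `CHARGE=3+ and 4+` dialect accepted by OMSSA-era tools; otherwise the
#' spectrum's own precursor charge is written when known.
#'
#' @param spectra A list of [etd_spectrum()] objects (or a single one).
#' @param path Output file path.
#' @param assignments Optional list of `charge_assignment` objects (from
#'   [assign_charges()]), parallel to `spectra`.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path, assignments = NULL) {
  if (inherits(spectra, "etd_spectrum")) spectra <- list(spectra)
  if (!is.null(assignments) && length(assignments) != length(spectra))
    stop("`assignments` must be parallel to `spectra`")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    charges <- if (!is.null(assignments)) assignments[[i]]$charges
               else if (!is.na(sp$precursor_charge)) sp$precursor_charge
               else integer(0)
    block <- c(
      "BEGIN IONS",
      paste0("TITLE=", sp$scan_id),
      sprintf("PEPMASS=%.4f", sp$precursor_mz),
      if (length(charges))
        paste0("CHARGE=", paste0(charges, "+", collapse = " and ")),
      sprintf("%.4f %.4f", sp$mz, sp$intensity),
      "END IONS", "")
    writeLines(block, con)
  }
  invisible(path)
}
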