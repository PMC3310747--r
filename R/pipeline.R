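#' Configuration for the end-to-end preprocessing pipeline
#'
#' @param input Path to an input MGF file, or a list of [etd_spectrum()]
#'   objects.
#' @param output_mgf Optional path for the filtered MGF.
#' @param assignments_tsv Optional path for the per-spectrum charge
#'   assignment table.
#' @param model A `charge_lda` model (or path to one written by
#'   [write_charge_model()]), or `NULL` to skip charge determination and
#'   use each spectrum's recorded charge.
#' @param precursor_params A [precursor_filter_params()] object.
#' @param noise_params A [noise_filter_params()] object.
#' @param strategy,t1,t2,full_range Passed to [assign_charges()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, output_mgf = NULL, assignments_tsv = NULL,
                            model = NULL,
                            precursor_params = precursor_filter_params(),
                            noise_params = noise_filter_params(),
                            strategy = "all", t1 = 0.99, t2 = 0.9,
                            full_range = 3:7) {
  if (is.character(model)) model <- read_charge_model(model)
  structure(list(input = input, output_mgf = output_mgf,
                 assignments_tsv = assignments_tsv, model = model,
                 precursor_params = precursor_params,
                 noise_params = noise_params, strategy = strategy,
                 t1 = t1, t2 = t2, full_range = full_range),
            class = "pipeline_config")
}

#' Run the full preprocessing pipeline
#'
#' For each spectrum, in this fixed order: (1) charge determination on the
#' RAW spectrum — the CP/NL features live in exactly the regions the
#' precursor filter removes, so features must be extracted first; (2)
#' precursor filtering under the largest assigned charge; (3) two-stage
#' noise filtering. The emitted peak list is the union of the 1+ and 2+
#' noise-filter views, since a surviving peak is a plausible product ion
#' at either charge.
#'
#' @param config A [pipeline_config()] object.
#' @return A list of class `pipeline_summary`: `n_input`, `n_processed`,
#'   `n_skipped`, `charge_histogram` (best assigned charge),
#'   `set_size_histogram` (1/2/all outcome counts), `peaks_in`,
#'   `peaks_after_precursor`, `peaks_after_noise`, plus `spectra`
#'   (filtered) and `assignments`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  spectra <- if (is.character(config$input)) read_mgf(config$input)
             else config$input
  n_input <- length(spectra)
  ok <- vapply(spectra, function(s) tic(s) > 0, logical(1))
  if (any(!ok))
    warning(sum(!ok), " spectra with zero total ion current skipped")
  spectra <- spectra[ok]

  assignments <- vector("list", length(spectra))
  filtered <- vector("list", length(spectra))
  peaks_in <- 0L; peaks_pf <- 0L; peaks_nf <- 0L
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    peaks_in <- peaks_in + n_peaks(sp)
    if (!is.null(config$model)) {
      post <- posterior_charge(config$model,
                               extract_features(sp, config$model$feature_params))
      assignments[[i]] <- assign_charges(post[1, ], config$strategy,
                                         config$t1, config$t2,
                                         config$full_range, sp$scan_id)
    } else {
      if (is.na(sp$precursor_charge))
        stop("spectrum ", sp$scan_id, " has unknown charge and no model ",
             "was supplied")
      assignments[[i]] <- structure(
        list(scan_id = sp$scan_id, charges = sp$precursor_charge,
             posterior = stats::setNames(1, sp$precursor_charge),
             strategy = "given", t1 = NA, t2 = NA),
        class = "charge_assignment")
    }
    n_filter <- max(assignments[[i]]$charges)
    pf <- apply_precursor_filter(sp, n_filter, config$precursor_params)
    peaks_pf <- peaks_pf + n_peaks(pf)
    nf <- apply_noise_filter(pf, config$noise_params)
    keep_mz <- sort(union(nf$singly$mz, nf$doubly$mz))
    out <- subset_peaks(nf$deisotoped, nf$deisotoped$mz %in% keep_mz)
    peaks_nf <- peaks_nf + n_peaks(out)
    filtered[[i]] <- out
  }

  if (!is.null(config$output_mgf))
    write_mgf(filtered, config$output_mgf, assignments)
  if (!is.null(config$assignments_tsv))
    utils::write.table(assignment_table(assignments), config$assignments_tsv,
                       sep = "\t", quote = FALSE, row.names = FALSE)

  best <- vapply(assignments, function(a)
    a$charges[which.max(a$posterior[as.character(a$charges)])], numeric(1))
  sizes <- vapply(assignments, function(a) length(a$charges), integer(1))
  size_label <- ifelse(sizes == 1, "1", ifelse(sizes == 2, "2", "all"))
  structure(list(
    n_input = n_input, n_processed = length(spectra),
    n_skipped = n_input - length(spectra),
    charge_histogram = table(best),
    set_size_histogram = table(factor(size_label, levels = c("1", "2", "all"))),
    peaks_in = peaks_in, peaks_after_precursor = peaks_pf,
    peaks_after_noise = peaks_nf,
    spectra = filtered, assignments = assignments),
    class = "pipeline_summary")
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat(sprintf("Pipeline: %d spectra in, %d processed, %d skipped\n",
              x$n_input, x$n_processed, x$n_skipped))
  cat(sprintf("  peaks: %d raw -> %d after precursor filter -> %d after noise filter\n",
              x$peaks_in, x$peaks_after_precursor, x$peaks_after_noise))
  cat("  assignment set sizes:",
      paste(names(x$set_size_histogram), as.integer(x$set_size_histogram),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Flatten charge assignments into a data frame
#'
#' @param assignments List of `charge_assignment` objects.
#' @return Data frame with columns `scan_id`, `charges` (`"3"` or
#'   `"3+4"`-style), `n_charges`, `best`, `best_posterior`, `strategy`.
#' @export
assignment_table <- function(assignments) {
  data.frame(
    scan_id = vapply(assignments, function(a) a$scan_id, character(1)),
    charges = vapply(assignments, function(a)
      paste(a$charges, collapse = "+"), character(1)),
    n_charges = vapply(assignments, function(a)
      length(a$charges), integer(1)),
    best = vapply(assignments, function(a)
      a$charges[which.max(a$posterior[as.character(a$charges)])], numeric(1)),
    best_posterior = vapply(assignments, function(a)
      max(a$posterior), numeric(1)),
    strategy = vapply(assignments, function(a) a$strategy, character(1)))
}

#' Evaluate charge assignments against ground truth
#'
#' A spectrum is misclassified when its true charge is not in the assigned
#' candidate set; the confusion matrix uses the best (highest-posterior)
#' assigned charge.
#'
#' @param assignments List of `charge_assignment` objects.
#' @param truth Either an integer vector of true charges parallel to
#'   `assignments`, or a data frame with `scan_id` and `charge` columns.
#' @return A list of class `charge_evaluation`: `misclassification_rate`
#'   (fraction with true charge outside the assigned set), `top1_error`
#'   (best-charge error rate), `confusion` (true x best table), `n`.
#' @export
evaluate_assignments <- function(assignments, truth) {
  if (is.data.frame(truth)) {
    idx <- match(vapply(assignments, function(a) a$scan_id, character(1)),
                 truth$scan_id)
    if (anyNA(idx)) stop("truth table is missing some scan ids")
    truth <- truth$charge[idx]
  }
  if (length(truth) != length(assignments))
    stop("`truth` must be parallel to `assignments`")
  in_set <- mapply(function(a, t) t %in% a$charges, assignments, truth)
  best <- vapply(assignments, function(a)
    a$charges[which.max(a$posterior[as.character(a$charges)])], numeric(1))
  lev <- sort(union(truth, best))
  structure(list(
    misclassification_rate = mean(!in_set),
    top1_error = mean(best != truth),
    confusion = table(true = factor(truth, lev), best = factor(best, lev)),
    n = length(truth)),
    class = "charge_evaluation")
}

#' @export
print.charge_evaluation <- function(x, ...) {
  cat(sprintf("Charge evaluation on %d spectra\n", x$n))
  cat(sprintf("  misclassification (true charge outside assigned set): %.2f%%\n",
              100 * x$misclassification_rate))
  cat(sprintf("  best-charge error: %.2f%%\n", 100 * x$top1_error))
  print(x$confusion)
  invisible(x)
}
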