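#' Parameters for charge-determination feature extraction
#'
#' Two spectral features carry the precursor-charge signal in ETD data:
#' the charge-reduced precursor (CP) peaks at MH(z+), and their neutral
#' losses (NL) at MH(z+) - N2/z. For each candidate charge c, intensity is
#' summed over that hypothesis's CP and NL windows and normalised by the
#' total ion current.
#'
#' @param W Divisor of the mass-proportional upstream CP window extent,
#'   shared with the precursor filter. Default 500.
#' @param tolp Tolerance in Da added around the CP windows. Default 2.
#' @param tol Half-width in Da (scaled by 1/z) of the NL windows. Default
#'   4, so the z = 1 window spans -22..-14 Da from MH(1+), covering both
#'   water (-18) and ammonia (-17) losses.
#' @param N2 Neutral-loss offset in Da. Default 18.
#' @param charges Ascending integer vector of candidate charge states.
#'   Default 3:7, the range typical of ETD precursors.
#' @param features Which feature families to extract: `"cp"`, `"nl"`, or
#'   both (default).
#' @return A list of class `charge_feature_params`.
#' @export
charge_feature_params <- function(W = 500, tolp = 2, tol = 4, N2 = 18,
                                  charges = 3:7,
                                  features = c("cp", "nl")) {
  features <- match.arg(features, c("cp", "nl"), several.ok = TRUE)
  if (tolp <= 0 || tol <= 0) stop("tolp and tol must be positive")
  if (length(charges) == 0 || any(charges < 1) ||
      any(charges != round(charges)) || is.unsorted(charges, strictly = TRUE))
    stop("`charges` must be a non-empty strictly ascending set of positive integers")
  structure(list(W = W, tolp = tolp, tol = tol, N2 = N2,
                 charges = as.integer(charges), features = features),
            class = "charge_feature_params")
}

#' Charge-reduced precursor feature windows for one charge hypothesis
#'
#' Under hypothesis c the neutral mass is M = c*(precursor_mz - H); the CP
#' windows are (MH(z+) - tolp/z, MH(z+) + M/(W*z) + tolp/z) for z = 1..c.
#' The mass-proportional term M/(W*z) accommodates the widening isotopic
#' envelope of heavier peptides.
#'
#' @param precursor_mz Observed precursor m/z in Thomson.
#' @param c Hypothesised precursor charge.
#' @param params A [charge_feature_params()] object.
#' @inheritParams mh
#' @return Data frame with columns `z`, `lo`, `hi`, `center`.
#' @export
cp_feature_windows <- function(precursor_mz, c,
                               params = charge_feature_params(),
                               proton = PROTON_MASS) {
  stopifnot(inherits(params, "charge_feature_params"))
  if (length(c) != 1L || c < 1 || c != round(c))
    stop("hypothesised charge `c` must be a single positive integer")
  M <- neutral_mass(precursor_mz, c, proton = proton)
  z <- seq_len(c)
  center <- mh(M, z, proton = proton)
  data.frame(z = z,
             lo = center - params$tolp / z,
             hi = center + M / (params$W * z) + params$tolp / z,
             center = center)
}

#' Neutral-loss feature windows for one charge hypothesis
#'
#' Windows of half-width tol/z centred at MH(z+) - N2/z for z = 1..c. The
#' 1/z scaling of both offset and width reflects that a fixed-mass neutral
#' loss moves the m/z of a z-charged ion by loss/z. These narrow bins keep
#' only the water/ammonia loss region, rather than the broad sweep the
#' precursor *filter* removes, because here the goal is discriminating
#' charge hypotheses, not cleaning the spectrum.
#'
#' @inheritParams cp_feature_windows
#' @return Data frame with columns `z`, `lo`, `hi`, `center`.
#' @export
nl_feature_windows <- function(precursor_mz, c,
                               params = charge_feature_params(),
                               proton = PROTON_MASS) {
  stopifnot(inherits(params, "charge_feature_params"))
  if (length(c) != 1L || c < 1 || c != round(c))
    stop("hypothesised charge `c` must be a single positive integer")
  M <- neutral_mass(precursor_mz, c, proton = proton)
  z <- seq_len(c)
  center <- mh(M, z, proton = proton) - params$N2 / z
  data.frame(z = z,
             lo = center - params$tol / z,
             hi = center + params$tol / z,
             center = center)
}

#' Extract TIC-normalised CP and NL features for every candidate charge
#'
#' For each candidate charge c, sums the intensity of peaks strictly inside
#' any CP window (feature `cp<c>`) and any NL window (`nl<c>`) of that
#' hypothesis, each divided by the spectrum's total ion current. All
#' components therefore lie in [0, 1]. Features are computed on the raw
#' spectrum: the precursor filter must not be applied first, since it would
#' remove exactly the peaks these features measure.
#'
#' @param spectrum An [etd_spectrum()] with positive total ion current.
#' @param params A [charge_feature_params()] object.
#' @inheritParams mh
#' @return Named numeric vector, e.g. `cp3..cp7, nl3..nl7` for the default
#'   candidate range and both feature families.
#' @export
extract_features <- function(spectrum, params = charge_feature_params(),
                             proton = PROTON_MASS) {
  stopifnot(inherits(spectrum, "etd_spectrum"),
            inherits(params, "charge_feature_params"))
  total <- tic(spectrum)
  if (total <= 0) stop("spectrum has zero total ion current")
  out <- numeric(0)
  if ("cp" %in% params$features) {
    cp <- vapply(params$charges, function(c) {
      win <- cp_feature_windows(spectrum$precursor_mz, c, params, proton)
      sum(spectrum$intensity[in_any_window(spectrum$mz, win)])
    }, numeric(1))
    names(cp) <- paste0("cp", params$charges)
    out <- c(out, cp)
  }
  if ("nl" %in% params$features) {
    nl <- vapply(params$charges, function(c) {
      win <- nl_feature_windows(spectrum$precursor_mz, c, params, proton)
      sum(spectrum$intensity[in_any_window(spectrum$mz, win)])
    }, numeric(1))
    names(nl) <- paste0("nl", params$charges)
    out <- c(out, nl)
  }
  out / total
}

#' Feature matrix for a collection of spectra
#'
#' @param spectra List of [etd_spectrum()] objects.
#' @param params A [charge_feature_params()] object.
#' @inheritParams mh
#' @return Numeric matrix, one row per spectrum, rownames from `scan_id`.
#' @export
extract_feature_matrix <- function(spectra, params = charge_feature_params(),
                                   proton = PROTON_MASS) {
  X <- t(vapply(spectra, extract_features,
                numeric(length(params$features) * length(params$charges)),
                params = params, proton = proton))
  rownames(X) <- vapply(spectra, function(s) s$scan_id, character(1))
  X
}

#' Fit a linear discriminant model over precursor charge classes
#'
#' Standard LDA with a shared (pooled) within-class covariance: class k
#' gets mean vector mu_k and prior pi_k; the pooled covariance is the
#' within-class scatter divided by (N - K), plus a small ridge on the
#' diagonal to guarantee invertibility when features are collinear (CP
#' sums of a charge and its multiple are nearly so on some spectra).
#'
#' @param X Numeric feature matrix, one row per spectrum (as produced by
#'   [extract_feature_matrix()]).
#' @param y Vector of true charge labels, one per row of `X`. Every class
#'   must have at least 2 samples and there must be at least 2 classes.
#' @param priors Optional named vector of class prior probabilities
#'   (names = charge labels); defaults to the empirical class frequencies.
#' @param ridge Diagonal regulariser added to the pooled covariance.
#'   Default `1e-6 * trace(Sigma) / ncol(X)`.
#' @param feature_params The [charge_feature_params()] the features were
#'   extracted with; stored so prediction can re-extract consistently.
#' @return An object of class `charge_lda` with elements `classes`,
#'   `means`, `cov` (ridged pooled covariance), `cov_inv`, `priors`,
#'   `ridge`, `feature_params`.
#' @export
fit_charge_lda <- function(X, y, priors = NULL, ridge = NULL,
                           feature_params = charge_feature_params()) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("`X` must be a numeric matrix")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  y <- factor(y)
  counts <- table(y)
  if (length(counts) < 2L) stop("need at least 2 charge classes to fit LDA")
  if (any(counts < 2L))
    stop("every charge class needs at least 2 training spectra; class(es) ",
         paste(names(counts)[counts < 2], collapse = ", "), " too small")
  N <- nrow(X)
  K <- length(counts)
  p <- ncol(X)
  means <- do.call(rbind, lapply(levels(y), function(k) colMeans(X[y == k, , drop = FALSE])))
  rownames(means) <- levels(y)
  scatter <- matrix(0, p, p)
  for (k in levels(y)) {
    Xc <- sweep(X[y == k, , drop = FALSE], 2, means[k, ])
    scatter <- scatter + crossprod(Xc)
  }
  sigma <- scatter / (N - K)
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(sigma)) / p
  sigma <- sigma + diag(ridge, p)
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("pooled covariance is singular even after ridge regularisation"))
  if (is.null(priors)) {
    priors <- as.numeric(counts) / N
    names(priors) <- levels(y)
  } else {
    if (is.null(names(priors)) || !setequal(names(priors), levels(y)))
      stop("`priors` must be named with the charge class labels")
    priors <- priors[levels(y)] / sum(priors)
  }
  structure(
    list(classes = as.integer(levels(y)), means = means,
         cov = sigma, cov_inv = chol2inv(ch), priors = priors,
         ridge = ridge, feature_params = feature_params,
         feature_names = colnames(X)),
    class = "charge_lda")
}

#' Posterior charge-state probabilities under a fitted LDA model
#'
#' Evaluates the linear discriminants
#' `delta_k(x) = x' Sigma^-1 mu_k - mu_k' Sigma^-1 mu_k / 2 + log pi_k`
#' and converts them to posteriors by a numerically stable softmax.
#'
#' @param model A `charge_lda` model from [fit_charge_lda()].
#' @param x A feature vector, or a matrix with one feature vector per row.
#' @return A probability matrix (rows sum to 1), columns named by charge.
#' @export
posterior_charge <- function(model, x) {
  stopifnot(inherits(model, "charge_lda"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$means))
    stop("feature dimension mismatch: model expects ", ncol(model$means),
         ", got ", ncol(x))
  A <- model$cov_inv %*% t(model$means)              # p x K
  const <- -0.5 * colSums(t(model$means) * A) + log(model$priors)
  scores <- sweep(x %*% A, 2, const, "+")            # n x K
  scores <- scores - apply(scores, 1, max)
  post <- exp(scores)
  post <- post / rowSums(post)
  colnames(post) <- rownames(model$means)
  post
}

#' @export
print.charge_lda <- function(x, ...) {
  cat(sprintf("Linear discriminant charge model: classes %s, %d features\n",
              paste0(x$classes, "+", collapse = " "), ncol(x$means)))
  cat("  priors:", paste(sprintf("%s+=%.3f", names(x$priors), x$priors),
                         collapse = " "), "\n")
  invisible(x)
}

#' Predict charge posteriors for spectra
#'
#' Extracts features with the model's stored parameters and returns the
#' posterior matrix plus the best class per spectrum.
#'
#' @param object A `charge_lda` model.
#' @param spectra A list of [etd_spectrum()] objects (or a single one).
#' @param ... Unused.
#' @return List with `posterior` (matrix) and `best` (integer vector).
#' @export
predict.charge_lda <- function(object, spectra, ...) {
  if (inherits(spectra, "etd_spectrum")) spectra <- list(spectra)
  X <- extract_feature_matrix(spectra, object$feature_params)
  post <- posterior_charge(object, X)
  best <- object$classes[max.col(post, ties.method = "first")]
  list(posterior = post, best = best)
}

#' Turn posterior probabilities into a charge assignment
#'
#' Three strategies, driven by the posterior probability p of the best
#' predicted charge:
#' \describe{
#'   \item{`"top1"`}{always assign the single best charge.}
#'   \item{`"top2"`}{(Top 1/Top 2) assign the best charge if p >= t1,
#'     otherwise the top two charges.}
#'   \item{`"all"`}{(1/2/All) assign the best charge if p > t1, the top
#'     two if t2 <= p <= t1, and the entire search range (ascending) if
#'     p < t2 — the spectrum then gets a range search.}
#' }
#' Ties in posterior are broken in favour of the lower charge.
#'
#' @param posteriors Named probability vector over charge classes (names
#'   are the charges), or a matrix with one spectrum per row.
#' @param strategy `"top1"`, `"top2"` or `"all"`.
#' @param t1 Upper posterior threshold, default 0.99.
#' @param t2 Lower posterior threshold, default 0.9. Must satisfy t1 > t2.
#' @param full_range Charges assigned when the classifier abstains under
#'   `"all"`. Default 3:7.
#' @param scan_id Identifier(s) carried into the assignment.
#' @return A `charge_assignment` (list with `scan_id`, `charges`,
#'   `posterior`, `strategy`, `t1`, `t2`), or a list of them for matrix
#'   input.
#' @export
assign_charges <- function(posteriors, strategy = c("all", "top1", "top2"),
                           t1 = 0.99, t2 = 0.9, full_range = 3:7,
                           scan_id = "") {
  strategy <- match.arg(strategy)
  if (t1 <= t2) stop("thresholds must satisfy t1 > t2")
  if (is.matrix(posteriors)) {
    ids <- if (length(scan_id) == nrow(posteriors)) scan_id
           else rep_len(scan_id, nrow(posteriors))
    return(lapply(seq_len(nrow(posteriors)), function(i)
      assign_charges(posteriors[i, ], strategy, t1, t2, full_range, ids[i])))
  }
  if (is.null(names(posteriors)))
    stop("`posteriors` must be named by charge state")
  if (abs(sum(posteriors) - 1) > 1e-6)
    stop("posteriors must sum to 1")
  chg <- as.integer(names(posteriors))
  ord <- order(-posteriors, chg)
  best_p <- posteriors[ord[1]]
  top2 <- chg[ord[seq_len(min(2L, length(chg)))]]
  charges <- switch(strategy,
    top1 = chg[ord[1]],
    top2 = if (best_p >= t1) chg[ord[1]] else top2,
    all  = if (best_p > t1) chg[ord[1]]
           else if (best_p >= t2) top2
           else sort(as.integer(full_range)))
  structure(list(scan_id = scan_id, charges = charges,
                 posterior = posteriors, strategy = strategy,
                 t1 = t1, t2 = t2),
            class = "charge_assignment")
}

#' @export
print.charge_assignment <- function(x, ...) {
  cat(sprintf("Charge assignment [%s]: %s (best posterior %.3f)\n",
              x$strategy, paste0(x$charges, "+", collapse = " and "),
              max(x$posterior)))
  invisible(x)
}

#' Write a fitted charge model to a plain-text file
#'
#' Serialises classes, priors, means, pooled covariance, ridge and feature
#' parameters as a tagged key-value text file at full double precision, so
#' a prediction run is reproducible without retraining.
#'
#' @param model A `charge_lda` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_charge_model <- function(model, path) {
  stopifnot(inherits(model, "charge_lda"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  fp <- model$feature_params
  lines <- c(
    "# etdprep charge_lda model v1",
    paste("classes:", paste(model$classes, collapse = " ")),
    paste("features:", paste(fp$features, collapse = " ")),
    paste("charges:", paste(fp$charges, collapse = " ")),
    paste("W:", num(fp$W)), paste("tolp:", num(fp$tolp)),
    paste("tol:", num(fp$tol)), paste("N2:", num(fp$N2)),
    paste("ridge:", num(model$ridge)),
    paste("priors:", num(model$priors)),
    paste("feature_names:", paste(model$feature_names, collapse = " ")),
    vapply(seq_len(nrow(model$means)), function(k)
      paste0("mean[", rownames(model$means)[k], "]: ", num(model$means[k, ])),
      character(1)),
    vapply(seq_len(nrow(model$cov)), function(i)
      paste0("cov[", i, "]: ", num(model$cov[i, ])), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a charge model written by [write_charge_model()]
#'
#' @param path Path to a model file.
#' @return A `charge_lda` model.
#' @export
read_charge_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  get1 <- function(k) vals[keys == k][1]
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  classes <- as.integer(nums(get1("classes")))
  fp <- charge_feature_params(
    W = nums(get1("W")), tolp = nums(get1("tolp")), tol = nums(get1("tol")),
    N2 = nums(get1("N2")),
    charges = as.integer(nums(get1("charges"))),
    features = strsplit(trimws(get1("features")), "\\s+")[[1]])
  feature_names <- strsplit(trimws(get1("feature_names")), "\\s+")[[1]]
  p <- length(feature_names)
  means <- do.call(rbind, lapply(classes, function(k)
    nums(get1(paste0("mean[", k, "]")))))
  rownames(means) <- classes
  colnames(means) <- feature_names
  sigma <- do.call(rbind, lapply(seq_len(p), function(i)
    nums(get1(paste0("cov[", i, "]")))))
  priors <- nums(get1("priors"))
  names(priors) <- classes
  structure(
    list(classes = classes, means = means, cov = sigma,
         cov_inv = chol2inv(chol(sigma)), priors = priors,
         ridge = nums(get1("ridge")), feature_params = fp,
         feature_names = feature_names),
    class = "charge_lda")
}
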