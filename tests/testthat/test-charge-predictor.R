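test_that("CP feature windows follow the mass-proportional construction", {
  # a 2000 Da peptide observed as its MH(2+): X = 2 Da at z = 2, tolp/z = 1,
  # so the z = 2 window is (MH(2+) - 1, MH(2+) + 3)
  pmz <- mh(2000, 2)
  w <- cp_feature_windows(pmz, 2)
  expect_equal(w$center[2] - w$lo[2], 1)
  expect_equal(w$hi[2] - w$center[2], 3)
  # z = 1: X = 4 Da, tolp = 2
  expect_equal(w$hi[1] - w$center[1], 6)
  expect_equal(nrow(cp_feature_windows(700, 1)), 1L)
  # Figure-1 case: windows centred at the 3+ reduced series
  w3 <- cp_feature_windows(492.2, 3)
  expect_equal(w3$center, c(1474.6, 737.8, 492.2), tolerance = 0.05 / 492.2)
})

test_that("NL windows reproduce the 2+ vs 4+ toy disambiguation (H = 1)", {
  # 300 m/z at 2+: MH(1+) bin at 599, water loss centred at 581
  w2 <- nl_feature_windows(300, 2, proton = 1)
  expect_identical(mh(neutral_mass(300, 2, proton = 1), 1, proton = 1), 599)
  expect_identical(w2$center[1], 581)
  # same precursor at 4+: MH(2+) also 599, but loss centred at 590
  w4 <- nl_feature_windows(300, 4, proton = 1)
  expect_identical(w4$center[2], 590)
  # z = 1 window spans -22..-14 Da from MH(1+): water and ammonia both in
  expect_equal(w2$lo[1], 599 - 22)
  expect_equal(w2$hi[1], 599 - 14)
})

test_that("features are TIC-normalised sums over hypothesis windows", {
  ser <- reduced_precursor_series(492.2, 3)$mz
  sp <- etd_spectrum(ser, c(100, 80, 60), precursor_mz = 492.2)
  fp <- charge_feature_params(charges = 3:4, features = "cp")
  f <- extract_features(sp, fp)
  expect_equal(unname(f["cp3"]), 1.0)
  expect_lt(f["cp4"], 1.0)  # hyp-4 windows at 1965.8/983.4/655.9 are empty
  expect_equal(unname(f["cp4"]), 60 / 240)  # only the shared 492.2 peak
  # all components in [0, 1]
  expect_true(all(f >= 0 & f <= 1))
  # a spectrum with no peaks near any window gives the zero vector
  far <- etd_spectrum(c(150, 1800), c(5, 5), precursor_mz = 492.2)
  expect_equal(unname(extract_features(far, charge_feature_params())),
               rep(0, 10))
  zero <- etd_spectrum(c(100, 200), c(0, 0), precursor_mz = 492.2)
  expect_error(extract_features(zero), "zero total ion current")
})

test_that("CP features are blind to charge multiples, NL features are not", {
  # toy spectrum (H = 1): the 599 CP bin is shared by the 2+ and 4+
  # hypotheses of a 300 m/z precursor; the loss peaks are not
  fp <- charge_feature_params(charges = c(2L, 4L))
  sp_nl2 <- etd_spectrum(c(599, 581), c(100, 30), precursor_mz = 300)
  f <- extract_features(sp_nl2, fp, proton = 1)
  expect_equal(unname(f["cp2"]), unname(f["cp4"]))
  expect_gt(f["nl2"], 0)
  expect_equal(unname(f["nl4"]), 0)
})

test_that("posteriors equal a hand-computed Gaussian Bayes rule", {
  set.seed(405)
  n_per <- 10
  X <- rbind(matrix(stats::rnorm(2 * n_per, 0, 1), ncol = 2),
             matrix(stats::rnorm(2 * n_per, 4, 1), ncol = 2))
  y <- rep(c(3, 4), each = n_per)
  m <- fit_charge_lda(X, y, ridge = 0,
                      feature_params = charge_feature_params(charges = 3:4))
  # independent computation: pooled covariance and explicit densities
  mu3 <- colMeans(X[1:n_per, ]); mu4 <- colMeans(X[n_per + 1:n_per, ])
  S <- (crossprod(sweep(X[1:n_per, ], 2, mu3)) +
        crossprod(sweep(X[n_per + 1:n_per, ], 2, mu4))) / (2 * n_per - 2)
  dens <- function(x, mu) {
    d <- x - mu
    exp(-0.5 * drop(t(d) %*% solve(S) %*% d)) /
      (2 * pi * sqrt(det(S)))
  }
  for (i in c(1, 5, 12, 20)) {
    p3 <- 0.5 * dens(X[i, ], mu3)
    p4 <- 0.5 * dens(X[i, ], mu4)
    expect_equal(unname(posterior_charge(m, X[i, ])[1, ]),
                 c(p3, p4) / (p3 + p4), tolerance = 1e-9)
  }
})

test_that("posteriors agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(406)
  ds <- generate_dataset(160, generator_params(
    charge_probs = c("3" = 0.4, "4" = 0.4, "5" = 0.2)), seed = 406)
  fp <- charge_feature_params()
  X <- extract_feature_matrix(ds$spectra, fp)
  y <- ds$truth$charge
  m <- fit_charge_lda(X, y, ridge = 0, feature_params = fp)
  ref <- MASS::lda(X, grouping = y)
  pref <- predict(ref, X)$posterior
  pown <- posterior_charge(m, X)
  expect_equal(unname(pown), unname(pref), tolerance = 1e-6)
})

test_that("posterior geometry: symmetry, normalisation, equidistance", {
  X <- rbind(matrix(c(0, 0), 1), matrix(c(0, 0.1), 1), matrix(c(10, 10), 1),
             matrix(c(10, 10.1), 1))
  m <- fit_charge_lda(X[c(1, 2, 3, 4), ], c(3, 3, 5, 5),
                      feature_params = charge_feature_params(charges = c(3L, 5L)))
  # midpoint between the class means: posterior 1/2 each
  mid <- (m$means[1, ] + m$means[2, ]) / 2
  expect_equal(unname(posterior_charge(m, mid)[1, ]), c(0.5, 0.5),
               tolerance = 1e-6)
  # far beyond one mean: posterior concentrates
  expect_gt(posterior_charge(m, c(-20, -20))[1, "3"], 1 - 1e-6)
  # rows always sum to 1
  set.seed(7)
  Z <- matrix(stats::rnorm(20), ncol = 2)
  expect_equal(rowSums(posterior_charge(m, Z)), rep(1, 10), tolerance = 1e-12)
})

test_that("degenerate training input is rejected", {
  X <- matrix(stats::rnorm(20), ncol = 2)
  expect_error(fit_charge_lda(X, rep(3, 10)), "at least 2")
  expect_error(fit_charge_lda(X, c(rep(3, 9), 4)), "at least 2 training spectra")
  expect_error(fit_charge_lda(X, rep(3:4, 5), priors = c(a = 1, b = 1)),
               "named with the charge class labels")
})

test_that("assignment strategies follow the posterior thresholds", {
  p <- c("3" = 0.995, "4" = 0.004, "5" = 0.0005, "6" = 0.0004, "7" = 0.0001)
  expect_equal(assign_charges(p, "all")$charges, 3L)
  p2 <- c("3" = 0.95, "4" = 0.04, "5" = 0.005, "6" = 0.004, "7" = 0.001)
  expect_equal(assign_charges(p2, "all")$charges, c(3L, 4L))
  expect_equal(assign_charges(p2, "top2")$charges, c(3L, 4L))
  expect_equal(assign_charges(p2, "top1")$charges, 3L)
  p3 <- c("3" = 0.50, "4" = 0.30, "5" = 0.15, "6" = 0.04, "7" = 0.01)
  expect_equal(assign_charges(p3, "all")$charges, 3:7)
  expect_equal(assign_charges(p3, "top2")$charges, c(3L, 4L))
  # boundary semantics: exactly t1 under "all" gives top 2; under
  # "top1/top2" it gives the single best
  pb <- c("3" = 0.99, "4" = 0.01)
  expect_equal(assign_charges(pb, "all", full_range = 3:4)$charges, c(3L, 4L))
  expect_equal(assign_charges(pb, "top2")$charges, 3L)
  # ties prefer the lower charge
  pt <- c("3" = 0.48, "4" = 0.48, "5" = 0.04)
  expect_equal(assign_charges(pt, "top2")$charges, c(3L, 4L))
  expect_equal(assign_charges(pt, "top1")$charges, 3L)
  expect_error(assign_charges(p, t1 = 0.5, t2 = 0.9), "t1 > t2")
})

test_that("a written model file reproduces the model exactly", {
  set.seed(407)
  ds <- generate_dataset(80, generator_params(
    charge_probs = c("3" = 0.5, "4" = 0.5)), seed = 407)
  fp <- charge_feature_params(charges = 3:4)
  X <- extract_feature_matrix(ds$spectra, fp)
  m <- fit_charge_lda(X, ds$truth$charge, feature_params = fp)
  path <- withr::local_tempfile(fileext = ".txt")
  write_charge_model(m, path)
  m2 <- read_charge_model(path)
  expect_equal(m2$classes, m$classes)
  expect_equal(m2$means, m$means)
  expect_equal(m2$priors, m$priors)
  expect_equal(posterior_charge(m2, X), posterior_charge(m, X),
               tolerance = 1e-12)
})
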