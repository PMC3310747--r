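test_that("mass-proportional removal windows match direct substitution", {
  # upstream width M/(W*z): 4 Da at z=1 and 2 Da at z=2 for a 2000 Da peptide
  w <- omssa_removal_windows(2000, 2)
  expect_equal(w$hi[w$z == 1] - mh(2000, 1), 4)
  expect_equal(w$hi[w$z == 2] - mh(2000, 2), 2)
  # downstream neutral-loss extents 60 and 30 Da below MH(1+) and MH(2+)
  expect_equal(mh(2000, 1) - w$lo[w$z == 1], 60)
  expect_equal(mh(2000, 2) - w$lo[w$z == 2], 30)

  # full hand computation for the Figure-1 peptide mass at n = 3
  M <- 1473.58
  w3 <- omssa_removal_windows(M, 3)
  w3 <- w3[order(w3$z), ]
  centers <- (M + 1:3 * 1.007276466) / (1:3)
  expect_equal(centers - w3$lo, c(60, 30, 6))          # N1/1, N1/2, N2/3
  expect_equal(w3$hi - centers, M / (500 * (1:3)))     # 2.947, 1.474, 0.982
  expect_true(!is.unsorted(omssa_removal_windows(M, 3)$lo))
})

test_that("fixed-width comparison windows match direct substitution", {
  M <- 1473.58
  w <- good_removal_windows(M, 3)
  mh1 <- mh(M, 1)
  z1 <- w[abs(w$hi - (mh1 + 3.1)) < 1e-9, ]
  expect_equal(c(z1$lo, z1$hi), c(1471.5, 1477.7), tolerance = 0.1 / 1471.5)
  z1nl <- w[abs(w$hi - mh1) < 1e-9, ]
  expect_equal(c(z1nl$lo, z1nl$hi), c(1414.6, 1474.6), tolerance = 0.1 / 1414.6)
  # neutral-loss extent N1/z: 20 Da at z = 3
  z3 <- w[w$z == 3 & w$hi - w$lo > 6.3, ]
  expect_equal(z3$hi - z3$lo, 20)
  # two windows per charge-reduced species
  expect_equal(nrow(good_removal_windows(M, 1)), 2L)
  expect_equal(nrow(w), 6L)
})

test_that("filtering keeps exactly the peaks outside every removal window", {
  pmz <- 492.2
  n <- 3
  M <- neutral_mass(pmz, n)
  ser <- reduced_precursor_series(pmz, n)$mz
  fixture <- etd_spectrum(
    c(ser[1], ser[1] - 18, ser[2], ser[2] - 9, ser[3], 250.0, 1200.0),
    c(100, 40, 90, 30, 80, 10, 12),
    precursor_mz = pmz, precursor_charge = n)
  out <- apply_precursor_filter(fixture)
  expect_equal(out$mz, c(250.0, 1200.0))  # only the two fragments survive
  # agrees with the per-peak per-window oracle
  win <- omssa_removal_windows(M, n)
  expect_equal(fixture$mz[!oracle_removed_mask(fixture$mz, win)], out$mz)
})

test_that("boundary peaks survive: the window inequalities are strict", {
  pmz <- 492.2
  M <- neutral_mass(pmz, 3)
  edge <- mh(M, 1) - 60 / 1       # exactly on the lower boundary at z = 1
  sp <- etd_spectrum(c(edge, edge + 1e-9), c(5, 5),
                     precursor_mz = pmz, precursor_charge = 3)
  out <- apply_precursor_filter(sp)
  expect_true(edge %in% out$mz)            # on the boundary: retained
  expect_false((edge + 1e-9) %in% out$mz)  # just inside: removed
})

test_that("passthrough variant and unknown charge are handled", {
  sp <- etd_spectrum(c(100, 737.8, 900), c(1, 2, 3), precursor_mz = 492.2,
                     precursor_charge = 3)
  none <- apply_precursor_filter(sp, params = precursor_filter_params(variant = "none"))
  expect_equal(n_peaks(none), n_peaks(sp))
  unk <- etd_spectrum(c(100, 900), c(1, 2), precursor_mz = 492.2)
  expect_error(apply_precursor_filter(unk), "charge determination")
})

test_that("filtering is a subset operation, idempotent, and oracle-exact", {
  set.seed(401)
  for (variant in c("omssa", "good")) {
    params <- precursor_filter_params(variant = variant)
    for (rep in 1:60) {
      g <- generate_spectrum(generator_params())
      sp <- g$spectrum
      n <- g$truth$charge
      out <- apply_precursor_filter(sp, n, params)
      expect_true(all(out$mz %in% sp$mz))
      again <- apply_precursor_filter(out, n, params)
      expect_identical(again$mz, out$mz)
      win <- if (variant == "omssa")
        omssa_removal_windows(g$truth$neutral_mass, n, params)
      else good_removal_windows(g$truth$neutral_mass, n, params)
      expect_equal(out$mz, sp$mz[!oracle_removed_mask(sp$mz, win)])
    }
  }
})

test_that("removal windows of distinct charge-reduced species do not overlap", {
  for (M in seq(600, 6000, by = 600)) {
    for (n in 1:7) {
      w <- omssa_removal_windows(M, n)  # sorted by lo
      expect_true(all(w$lo[-1] >= w$hi[-nrow(w)] - 1e-9),
                  info = sprintf("M=%g n=%d", M, n))
    }
  }
})

test_that("parameter validation rejects inconsistent settings", {
  expect_error(precursor_filter_params(W = 0), "positive")
  expect_error(precursor_filter_params(N1 = 10, N2 = 20), "N1 must be >= N2")
})
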