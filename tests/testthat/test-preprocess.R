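test_that("bin grid defaults give 4000 half-open 0.1 Da bins over 600-1000", {
  g <- bin_grid()
  expect_equal(g$n_bins, 4000)
  expect_equal(g$labels[1], 600.0)
  expect_equal(g$labels[4000], 999.9)
  expect_error(bin_grid(600, 1000, 0.3), "exact integer")
})

test_that("lock-mass correction subtracts the observed offset from every peak", {
  s <- reims_spectrum(c(650.000, 699.520, 744.578), c(10, 100, 50), "b")
  out <- lock_mass_correct(s, reference = 699.497)
  expect_equal(out$lock_shift, 0.023)
  expect_equal(out$peaks$mz, c(650.000, 699.520, 744.578) - 0.023)
  # lock peak exactly at reference: identity transform
  s0 <- reims_spectrum(c(650, 699.497), c(1, 10), "b")
  expect_equal(lock_mass_correct(s0)$peaks$mz, c(650, 699.497))
  # the most intense candidate in the window wins
  s2 <- reims_spectrum(c(699.400, 699.520), c(5, 100), "b")
  expect_equal(lock_mass_correct(s2)$lock_shift, 0.023)
})

test_that("lock-mass correction is idempotent and warns when no lock peak exists", {
  s <- reims_spectrum(c(650.0, 699.55, 800.2), c(1, 10, 3), "b")
  once <- lock_mass_correct(s)
  twice <- lock_mass_correct(once)
  expect_equal(twice$peaks, once$peaks)
  expect_equal(twice$lock_shift, 0)
  far <- reims_spectrum(c(650, 801), c(1, 1), "b")
  expect_warning(out <- lock_mass_correct(far), "no lock-mass peak")
  expect_equal(out$peaks, far$peaks)
})

test_that("simulated calibration drift is exactly undone by lock-mass correction", {
  mz <- c(620.1, 699.497, 744.555, 910.42)
  s <- reims_spectrum(mz + 0.05, c(5, 100, 40, 2), "b")
  out <- lock_mass_correct(s, 699.497)
  expect_equal(out$peaks$mz, mz, tolerance = 1e-9)
})

test_that("background subtraction matches a brute-force quantile rule", {
  set.seed(8)
  mz <- sort(runif(60, 600, 1000))
  int <- rexp(60, 1 / 50)
  s <- reims_spectrum(mz, int, "b")
  out <- subtract_background(s, quantile = 0.05)
  base <- as.numeric(quantile(int, 0.05))
  keep <- int - base > 0
  o <- order(mz)
  expect_equal(out$peaks$mz, mz[o][keep[o]])
  expect_equal(out$peaks$intensity, (int - base)[o][keep[o]])
  # flat spectrum: everything equals the baseline and is removed
  flat <- reims_spectrum(c(650, 700, 750), c(5, 5, 5), "b")
  expect_equal(nrow(subtract_background(flat)$peaks), 0)
  # zero-quantile baseline is the minimum intensity
  s2 <- reims_spectrum(c(650, 700, 750), c(3, 9, 12), "b")
  expect_equal(subtract_background(s2, quantile = 0)$peaks$intensity,
               c(9 - 3, 12 - 3))
})

test_that("binning places peaks by half-open 0.1 Da intervals", {
  g <- bin_grid()
  v <- bin_spectrum(reims_spectrum(699.497, 10, "b"), g)
  expect_equal(unname(v[["699.4"]]), 10)
  expect_equal(sum(v), 10)
  v2 <- bin_spectrum(reims_spectrum(c(700.0499, 700.0501, 700.1000),
                                    c(5, 5, 5), "b"), g)
  expect_equal(unname(v2[["700.0"]]), 10)
  expect_equal(unname(v2[["700.1"]]), 5)
})

test_that("binning agrees with a brute-force accumulation loop and conserves intensity", {
  set.seed(15)
  mz <- runif(1000, 590, 1010)
  int <- rexp(1000)
  g <- bin_grid()
  v <- bin_spectrum(reims_spectrum(mz, int, "b"), g)
  ref <- numeric(g$n_bins)
  for (i in seq_along(mz)) {
    if (mz[i] < 600 || mz[i] >= 1000) next
    j <- findInterval(mz[i], seq(600, 1000, by = 0.1))
    ref[j] <- ref[j] + int[i]
  }
  expect_equal(unname(v), ref)
  in_window <- mz >= 600 & mz < 1000
  expect_equal(sum(v), sum(int[in_window]))
})

test_that("TIC normalization yields unit-sum rows and flags empty signal", {
  out <- normalize_tic(c(2, 2, 0, 4))
  expect_false(out$rejected)
  expect_equal(out$values, c(0.25, 0.25, 0, 0.5))
  expect_true(normalize_tic(numeric(4))$rejected)
  expect_true(normalize_tic(c(1, 2), signal_floor = 10)$rejected)
  set.seed(2)
  for (i in 1:20) {
    x <- rexp(50) * rexp(1, 1 / 100)
    expect_equal(sum(normalize_tic(x)$values), 1)
  }
  expect_error(normalize_tic(c(-1, 2)), "non-negative")
})

test_that("the cohort feature matrix is 4000 bins wide with QC logging", {
  co <- generate_cohort(two_class_config(seed = 31, burn_sd = 0.1,
                                         drift_sd = 0.02, background = 2,
                                         n_background = 20))
  weak <- reims_spectrum(c(699.497, 820.4), c(3, 1), "weak_burn",
                         tissue_class = "normal")
  co2 <- reims_cohort(c(co$spectra, list(weak)))
  expect_message(fm <- build_feature_matrix(co2), "weak_burn")
  expect_equal(ncol(fm$x), 4000)
  expect_equal(nrow(fm$x), length(co))
  expect_equal(fm$dropped$burn_id, "weak_burn")
  expect_true(all(abs(rowSums(fm$x) - 1) < 1e-12))
  expect_true(all(fm$x >= 0))
  expect_true(all(abs(fm$meta$lock_shift) < 0.1))
  expect_error(build_feature_matrix(reims_cohort(list())), "empty cohort")
})

test_that("preprocessing is row-order equivariant and scale invariant", {
  co <- generate_cohort(two_class_config(seed = 33, burn_sd = 0.2,
                                         drift_sd = 0.02, background = 2,
                                         n_background = 15))
  fm <- suppressMessages(build_feature_matrix(co))
  perm <- rev(seq_along(co$spectra))
  fm_perm <- suppressMessages(build_feature_matrix(co[perm]))
  expect_equal(fm_perm$x[rownames(fm$x), ], fm$x)
  # multiplying one burn's raw intensities by a constant changes nothing
  co$spectra[[1]]$peaks$intensity <- co$spectra[[1]]$peaks$intensity * 10
  fm10 <- suppressMessages(build_feature_matrix(co))
  expect_equal(fm10$x, fm$x, tolerance = 1e-12)
})
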