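test_that("PCA matches a brute-force eigendecomposition of the covariance", {
  set.seed(4)
  x <- matrix(rnorm(12 * 5), 12, 5)
  p <- fit_pca(x, n_pcs = 5)
  ev <- eigen(cov(x), symmetric = TRUE)
  sdev2 <- apply(p$scores, 2, var)
  expect_equal(unname(sdev2), ev$values[1:5], tolerance = 1e-9)
  expect_equal(p$evar, ev$values[1:5] / sum(ev$values), tolerance = 1e-9)
  # loadings orthonormal and aligned with eigenvectors up to sign
  expect_equal(crossprod(p$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  for (j in 1:5)
    expect_equal(abs(sum(p$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
})

test_that("the first loading follows the axis of maximal variance", {
  set.seed(5)
  x <- cbind(rnorm(40, sd = 5), rnorm(40, sd = 0.2), rnorm(40, sd = 0.2))
  p <- fit_pca(x, n_pcs = 2)
  expect_gt(abs(p$loadings[1, 1]), 0.99)
  # explained variance fractions are non-increasing on random matrices
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnorm(30 * 8), 30, 8)
    expect_true(all(diff(fit_pca(m, 8)$evar) <= 1e-12))
  }
})

test_that("n_pcs beyond the matrix rank is reduced with a warning", {
  x <- matrix(rnorm(6 * 10), 6, 10)
  expect_warning(p <- fit_pca(x, n_pcs = 9), "reduced")
  expect_equal(p$n_pcs, 5)
})

test_that("LDA recovers the between-class direction and rank constraints", {
  set.seed(6)
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 4), 30, 2))
  lab <- rep(c("a", "b"), each = 30)
  l <- fit_lda(x, lab)
  d <- (l$means["b", ] - l$means["a", ]); d <- d / sqrt(sum(d^2))
  expect_gt(abs(sum(l$ld_axes[, 1] * d)), 0.98)
  expect_equal(ncol(l$ld_axes), 1)
  l3 <- fit_lda(rbind(x, matrix(rnorm(60, c(0, 8)), 30, 2, byrow = TRUE)),
                c(lab, rep("c", 30)))
  expect_equal(ncol(l3$ld_axes), 2)
  expect_error(fit_lda(x[c(1, 31, 32), ], c("a", "b", "b")), "a")
})

test_that("posteriors equal brute-force Gaussian-Bayes densities", {
  set.seed(7)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 3), 20, 2))
  lab <- rep(c("a", "b"), each = 20)
  model <- fit_pclda(x, lab, n_pcs = 2, ridge = 0)
  q <- matrix(c(1.2, 0.4, -2, 1, 3.3, 2.8), ncol = 2, byrow = TRUE)
  pred <- predict(model, q)
  z <- sweep(q, 2, model$pca$center) %*% model$pca$loadings
  sw <- model$lda$cov
  dens <- sapply(c("a", "b"), function(cl) {
    d <- sweep(z, 2, model$lda$means[cl, ])
    exp(-0.5 * rowSums((d %*% solve(sw)) * d)) / (2 * pi * sqrt(det(sw)))
  })
  post <- dens * 0.5
  post <- post / rowSums(post)
  expect_equal(pred$posterior.a, unname(post[, "a"]), tolerance = 1e-9)
  expect_equal(pred$posterior.b, unname(post[, "b"]), tolerance = 1e-9)
  expect_equal(pred$reliability, unname(apply(post, 1, max)), tolerance = 1e-9)
})

test_that("classification boundary agrees with an independent LDA fit", {
  set.seed(9)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 2), 50, 2))
  lab <- rep(c("a", "b"), each = 50)
  model <- fit_pclda(x, lab, n_pcs = 2, ridge = 0)
  grid <- as.matrix(expand.grid(seq(-2, 4, 0.5), seq(-2, 4, 0.5)))
  colnames(grid) <- NULL
  ours <- predict(model, grid)$predicted
  ref <- MASS::lda(x, grouping = lab, prior = c(0.5, 0.5))
  theirs <- as.character(predict(ref, grid)$class)
  expect_equal(ours, theirs)
})

test_that("a spectrum at a class mean is called with near-certain posterior", {
  set.seed(10)
  x <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2), matrix(rnorm(100, 5, 0.3), 50, 2))
  lab <- rep(c("a", "b"), each = 50)
  model <- fit_pclda(x, lab, n_pcs = 2)
  pred <- predict(model, model$lda$means["a", ] %*% t(model$pca$loadings) +
                    model$pca$center)
  expect_equal(pred$predicted, "a")
  expect_gt(pred$posterior.a, 0.99)
})

test_that("an equidistant point splits posteriors and is not reported at 0.75", {
  x <- rbind(matrix(c(-1, -1, -1.2, -0.8, -0.9, -1.1), 3, 2, byrow = TRUE),
             matrix(c(1, 1, 1.2, 0.8, 0.9, 1.1), 3, 2, byrow = TRUE))
  lab <- rep(c("a", "b"), each = 3)
  model <- fit_pclda(x, lab, n_pcs = 2)
  mid <- (colMeans(x[1:3, ]) + colMeans(x[4:6, ])) / 2
  pred <- predict(model, mid, threshold = 0.75)
  expect_equal(pred$posterior.a, 0.5, tolerance = 1e-9)
  expect_equal(pred$reliability, 0.5, tolerance = 1e-9)
  expect_false(pred$reported)
})

test_that("row shuffling does not change the fitted predictions", {
  sc <- default_scenario()
  fm <- sc$features
  idx <- c(1:20, 61:80, 121:140)  # twenty spectra from each class
  sub <- fm$x[idx, ]
  lab <- fm$meta$tissue_class[idx]
  m1 <- suppressWarnings(fit_pclda(sub, lab, n_pcs = 10))
  perm <- sample(60)
  m2 <- suppressWarnings(fit_pclda(sub[perm, ], lab[perm], n_pcs = 10))
  expect_equal(predict(m1, fm$x[61:90, ])$predicted,
               predict(m2, fm$x[61:90, ])$predicted)
})

test_that("noiseless cohorts are classified perfectly and dims are checked", {
  co <- generate_cohort(two_class_config(seed = 41))
  fm <- suppressMessages(build_feature_matrix(co))
  model <- suppressWarnings(fit_pclda(fm, n_pcs = 5))
  pred <- predict(model, fm)
  expect_true(all(pred$predicted == fm$meta$tissue_class))
  expect_true(all(pred$reliability > 0.99))
  expect_error(predict(model, matrix(0, 1, 10)), "expects")
})
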