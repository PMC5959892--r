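test_that("percent reporting uses half-up rounding at one decimal", {
  expect_equal(round_half_up(100 * 38 / 39, 1), 97.4)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(93.05, 1), 93.1)
})

test_that("low-tumour cancer samples are excluded, others untouched", {
  mk <- function(id, cls, tc) reims_spectrum(c(699.497, 700.2), c(10, 5), id,
                                             tissue_class = cls,
                                             tumour_content = tc)
  co <- reims_cohort(list(mk("b1", "cancer", 40), mk("b2", "cancer", 50),
                          mk("b3", "cancer", 90), mk("b4", "normal", 0),
                          mk("b5", "normal", NA)))
  out <- filter_low_tumour(co, 50)
  expect_equal(cohort_meta(out)$burn_id, c("b2", "b3", "b4", "b5"))
  expect_equal(attr(out, "excluded"), "b1")
  co2 <- reims_cohort(list(mk("b1", "cancer", NA), mk("b2", "normal", NA)))
  expect_warning(out2 <- filter_low_tumour(co2, 50), "missing tumour content")
  expect_equal(cohort_meta(out2)$burn_id, "b2")
})

test_that("confusion metrics reproduce worked sensitivity/specificity examples", {
  # 4-class table: 39 cancer samples with 1 called peritoneum; 15 normal
  # ovary with 1 called fallopian tube; tube and peritoneum all correct
  classes <- c("cancer", "fallopian_tube", "normal_ovary", "peritoneum")
  cm <- matrix(0, 4, 4, dimnames = list(classes, classes))
  diag(cm) <- c(38, 15, 14, 14)
  cm["cancer", "peritoneum"] <- 1
  cm["normal_ovary", "fallopian_tube"] <- 1
  m <- metrics(as.table(cm))
  expect_equal(m$per_class$sensitivity_pct[m$per_class$class == "cancer"], 97.4)
  expect_equal(m$per_class$specificity_pct[m$per_class$class == "cancer"], 100)
  expect_equal(m$per_class$sensitivity_pct[m$per_class$class == "normal_ovary"],
               93.3)  # 1/15 misclassified = 6.7% error
  expect_equal(m$overall_pct, 97.6)
  # perfect diagonal
  perfect <- diag(c(5, 7, 9)); dimnames(perfect) <- list(letters[1:3], letters[1:3])
  mp <- metrics(as.table(perfect))
  expect_true(all(mp$per_class$sensitivity_pct == 100))
  expect_equal(mp$overall_pct, 100)
  # a class with zero true instances is undefined, not zero
  cm0 <- matrix(c(3, 0, 1, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_true(is.na(metrics(as.table(cm0))$per_class$sensitivity[2]))
})

test_that("recognition summary reproduces the reported/correct worked ratios", {
  set.seed(1)
  n <- 232
  rel <- c(runif(217, 0.76, 1), runif(15, 0.3, 0.74))
  truth <- rep("cancer", n)
  predicted <- truth
  predicted[c(5, 9)] <- "normal"   # 2 errors among the reported 217
  res <- data.frame(truth = truth, predicted = predicted, reliability = rel)
  s <- recognition_summary(res, threshold = 0.75)
  expect_equal(s$n_reported, 217)
  expect_equal(s$reported_pct, 93.5)
  expect_equal(s$n_correct, 215)
  expect_equal(s$accuracy_pct, 99.1)
  s0 <- recognition_summary(res, threshold = 1e-9)
  expect_equal(s0$n_reported, 232)
})

test_that("LOPOCV makes one fold per patient with zero patient leakage", {
  co <- generate_cohort(two_class_config(seed = 51, patients = 4, samples = 2,
                                         burns = 2, burn_sd = 0.2,
                                         patient_sd = 0.2, drift_sd = 0.02,
                                         background = 2, n_background = 10))
  cv <- lopocv(co, n_pcs = 5)
  m <- cohort_meta(co)
  expect_setequal(unique(cv$assignments$fold), unique(m$patient_id))
  # every burn predicted exactly once, in its own patient's fold
  expect_setequal(cv$assignments$burn_id, m$burn_id)
  own <- m$patient_id[match(cv$assignments$burn_id, m$burn_id)]
  expect_equal(cv$assignments$fold, own)
})

test_that("a cleanly separable cohort cross-validates at 100% sample accuracy", {
  co <- generate_cohort(two_class_config(seed = 53, fold = 8, patients = 4,
                                         samples = 2, burns = 2,
                                         patient_sd = 0, burn_sd = 0.1,
                                         drift_sd = 0.02, background = 1,
                                         n_background = 10))
  cv <- lopocv(co, n_pcs = 5)
  expect_equal(metrics(cv$confusion_sample)$overall, 1)
  # noiseless replicate: spectrum- and sample-level accuracies coincide
  co0 <- generate_cohort(two_class_config(seed = 54, patients = 3, burns = 2))
  cv0 <- lopocv(co0, n_pcs = 3)
  expect_equal(metrics(cv0$confusion_spectrum)$overall,
               metrics(cv0$confusion_sample)$overall)
})

test_that("cross-validated accuracy never beats resubstitution", {
  for (seed in c(61, 62)) {
    co <- generate_cohort(two_class_config(seed = seed, fold = 1.6,
                                           patients = 5, samples = 1,
                                           burns = 3, patient_sd = 0.4,
                                           burn_sd = 0.5, drift_sd = 0.02,
                                           background = 2, n_background = 15))
    cv <- lopocv(co, n_pcs = 5)
    fm <- suppressMessages(build_feature_matrix(co))
    model <- suppressWarnings(fit_pclda(fm, n_pcs = 5))
    resub <- mean(predict(model, fm)$predicted == fm$meta$tissue_class)
    lopo <- metrics(cv$confusion_spectrum)$overall
    expect_lte(lopo, resub + 1e-9)
  }
})

test_that("raising the reliability threshold does not hurt accuracy-among-reported on average", {
  th <- c(0.55, 0.75, 0.95)
  acc <- matrix(NA_real_, 20, length(th))
  for (r in 1:20) {
    co <- generate_cohort(two_class_config(seed = 700 + r, fold = 1.7,
                                           patients = 4, samples = 1,
                                           burns = 2, patient_sd = 0.3,
                                           burn_sd = 0.5, drift_sd = 0.02,
                                           background = 2, n_background = 10))
    cv <- lopocv(co, n_pcs = 4)
    asg <- cv$assignments
    for (j in seq_along(th)) {
      s <- recognition_summary(asg, threshold = th[j])
      acc[r, j] <- s$accuracy_among_reported
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  expect_true(all(diff(mean_acc) >= -0.02))
})

test_that("LOPOCV validates its inputs", {
  co <- generate_cohort(two_class_config(seed = 71, patients = 1))
  expect_error(lopocv(co), "3 patients")
})
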