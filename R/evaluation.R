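#' Round half away from zero
#'
#' Reported percentages use conventional half-up rounding (38/39 prints as
#' 97.4), not banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Exclude low-tumour-content cancer samples
#'
#' Cancer-class samples whose histopathology-reported viable tumour content
#' is below the cutoff are removed before model building, so training
#' spectra represent tumour rather than tumour-associated stroma. The
#' comparison is strict: a sample at exactly the cutoff is retained.
#' Cancer samples with missing content fail the filter (with a warning);
#' non-cancer classes are untouched.
#'
#' @param cohort A `reims_cohort`.
#' @param min_content Minimum percent viable tumour (default 50).
#' @param cancer_classes Labels treated as cancer.
#' @return Filtered `reims_cohort` with an `excluded` attribute listing the
#'   removed burn ids.
#' @export
filter_low_tumour <- function(cohort, min_content = 50,
                              cancer_classes = "cancer") {
  stopifnot(inherits(cohort, "reims_cohort"),
            min_content >= 0, min_content <= 100)
  m <- cohort_meta(cohort)
  is_cancer <- m$tissue_class %in% cancer_classes
  missing_tc <- is_cancer & is.na(m$tumour_content)
  if (any(missing_tc))
    warning("cancer burns with missing tumour content excluded: ",
            paste(m$burn_id[missing_tc], collapse = ", "))
  drop <- is_cancer & (is.na(m$tumour_content) | m$tumour_content < min_content)
  out <- reims_cohort(cohort$spectra[!drop], cohort$provenance)
  attr(out, "excluded") <- m$burn_id[drop]
  out
}

#' Confusion matrix over a fixed class set
#'
#' @param truth,predicted Label vectors of equal length.
#' @param classes Class set for both dimensions (default: union observed).
#' @return Integer table, true class x predicted class.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  table(truth = factor(truth, classes), predicted = factor(predicted, classes))
}

#' Classification metrics from a confusion matrix
#'
#' Per-class sensitivity (correct / total of that class), one-vs-rest
#' specificity (fraction of all other-class units not called as the class),
#' and overall correct classification (trace / total). Raw fractions are
#' retained alongside half-up percentages at one decimal. A class with zero
#' true units gets `NA` (undefined), not 0.
#'
#' @param confusion Square count table from [confusion_matrix()].
#' @return List with `per_class` (data.frame: class, n, sensitivity,
#'   specificity and their `_pct` renderings), `overall` and `overall_pct`.
#' @export
metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  stopifnot(nrow(cm) == ncol(cm), sum(cm) > 0)
  classes <- rownames(cm)
  n_true <- rowSums(cm)
  sens <- ifelse(n_true > 0, diag(cm) / n_true, NA_real_)
  spec <- vapply(seq_along(classes), function(i) {
    neg <- sum(cm[-i, , drop = FALSE])
    if (neg == 0) return(NA_real_)
    sum(cm[-i, -i, drop = FALSE]) / neg
  }, numeric(1))
  overall <- sum(diag(cm)) / sum(cm)
  list(per_class = data.frame(
         class = classes, n = as.integer(n_true),
         sensitivity = sens, specificity = spec,
         sensitivity_pct = round_half_up(100 * sens, 1),
         specificity_pct = round_half_up(100 * spec, 1),
         row.names = NULL, stringsAsFactors = FALSE),
       overall = overall,
       overall_pct = round_half_up(100 * overall, 1))
}

# majority vote over burns of one sample; ties broken by mean posterior
.sample_call <- function(pred_df, classes) {
  votes <- table(factor(pred_df$predicted, classes))
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1L) return(top)
  mp <- vapply(top, function(cl) mean(pred_df[[paste0("posterior.", cl)]]),
               numeric(1))
  top[which.max(mp)]
}

#' Leave-one-patient-out cross-validation of a PC-LDA model
#'
#' One fold per patient: all spectra of the held-out patient are predicted
#' by a model trained on all remaining patients' spectra, so no
#' within-patient information leaks into training. Sample-level calls are
#' majority votes over the sample's burns (ties broken by mean posterior).
#' A fold whose held-out truth class is absent from its training classes is
#' logged as degenerate and its spectra are excluded from the confusion
#' tables.
#'
#' @param cohort A `reims_cohort` (>= 3 patients; every class in >= 2
#'   patients).
#' @param grid A [bin_grid()].
#' @param n_pcs,ridge,priors Model settings, see [fit_pclda()].
#' @param threshold Reliability threshold for [predict.reims_pclda()].
#' @param lockmass,lock_window,background_quantile,signal_floor
#'   Preprocessing settings, see [build_feature_matrix()].
#' @return Object of class `reims_cv`: `assignments` (per-spectrum
#'   data.frame with fold, truth, prediction, posteriors, sample-level
#'   call), `confusion_spectrum`, `confusion_sample`, `degenerate_folds`
#'   and `dropped` (QC exclusions).
#' @export
lopocv <- function(cohort, grid = bin_grid(), n_pcs = 25, ridge = 1e-6,
                   priors = "equal", threshold = 0.75, lockmass = 699.497,
                   lock_window = 0.3, background_quantile = 0.05,
                   signal_floor = 10) {
  stopifnot(inherits(cohort, "reims_cohort"))
  fm <- suppressMessages(build_feature_matrix(
    cohort, grid, lockmass = lockmass, lock_window = lock_window,
    background_quantile = background_quantile, signal_floor = signal_floor))
  meta <- fm$meta
  patients <- unique(meta$patient_id)
  if (length(patients) < 3) stop("need at least 3 patients for LOPOCV")
  cls_pat <- tapply(meta$patient_id, meta$tissue_class,
                    function(p) length(unique(p)))
  if (any(cls_pat < 2))
    stop("every class must be present in >= 2 patients; offending: ",
         paste(names(cls_pat)[cls_pat < 2], collapse = ", "))
  res <- list(); degenerate <- character()
  for (pat in patients) {
    test_idx <- which(meta$patient_id == pat)
    train_idx <- which(meta$patient_id != pat)
    model <- suppressWarnings(fit_pclda(
      fm$x[train_idx, , drop = FALSE], meta$tissue_class[train_idx],
      n_pcs = n_pcs, ridge = ridge, priors = priors))
    pr <- predict(model, fm$x[test_idx, , drop = FALSE], threshold = threshold)
    pr$burn_id <- meta$burn_id[test_idx]
    pr$fold <- pat
    pr$truth <- meta$tissue_class[test_idx]
    pr$sample_id <- meta$sample_id[test_idx]
    pr$patient_id <- pat
    pr$degenerate <- !pr$truth %in% model$lda$classes
    if (any(pr$degenerate)) degenerate <- c(degenerate, pat)
    res[[pat]] <- pr
  }
  asg <- do.call(rbind, res)
  rownames(asg) <- NULL
  ok <- !asg$degenerate
  classes <- sort(unique(meta$tissue_class))
  conf_spec <- confusion_matrix(asg$truth[ok], asg$predicted[ok], classes)
  by_sample <- split(asg[ok, , drop = FALSE], asg$sample_id[ok])
  sample_call <- vapply(by_sample, .sample_call, character(1), classes = classes)
  sample_truth <- vapply(by_sample, function(d) d$truth[1], character(1))
  conf_sample <- confusion_matrix(sample_truth, sample_call, classes)
  asg$sample_call <- sample_call[asg$sample_id]
  structure(list(assignments = asg, confusion_spectrum = conf_spec,
                 confusion_sample = conf_sample,
                 sample_calls = data.frame(sample_id = names(by_sample),
                                           truth = sample_truth,
                                           call = sample_call,
                                           row.names = NULL,
                                           stringsAsFactors = FALSE),
                 degenerate_folds = unique(degenerate),
                 dropped = fm$dropped),
            class = "reims_cv")
}

#' @export
print.reims_cv <- function(x, ...) {
  m <- metrics(x$confusion_sample)
  cat(sprintf("<reims_cv> %d folds, sample-level correct classification %.1f%%\n",
              length(unique(x$assignments$fold)), m$overall_pct))
  print(x$confusion_sample)
  invisible(x)
}

#' Summarise thresholded real-time recognition
#'
#' Given per-burn recognition results with truth labels, computes the
#' fraction of sampling points reported at or above the reliability
#' threshold, and the correct-classification rate among those reported —
#' the two headline numbers of threshold-gated recognition.
#'
#' @param results data.frame with columns `truth`, `predicted` and
#'   `reliability` (e.g. [predict.reims_pclda()] output plus truth).
#' @param threshold Reliability threshold in `(0, 1)`.
#' @return List: `n_total`, `n_reported`, `n_correct`, `reported_pct`,
#'   `accuracy_pct` (among reported; `NA` when nothing is reported), raw
#'   fractions alongside.
#' @export
recognition_summary <- function(results, threshold = 0.75) {
  stopifnot(all(c("truth", "predicted", "reliability") %in% names(results)),
            threshold > 0, threshold < 1)
  rep_sel <- results$reliability >= threshold
  n_total <- nrow(results); n_rep <- sum(rep_sel)
  n_cor <- sum(results$predicted[rep_sel] == results$truth[rep_sel])
  list(n_total = n_total, n_reported = n_rep, n_correct = n_cor,
       reported_fraction = n_rep / n_total,
       reported_pct = round_half_up(100 * n_rep / n_total, 1),
       accuracy_among_reported = if (n_rep) n_cor / n_rep else NA_real_,
       accuracy_pct = if (n_rep) round_half_up(100 * n_cor / n_rep, 1) else NA_real_)
}
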