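#' False-discovery-rate adjustment of bin-wise p-values
#'
#' Default is the Benjamini-Yekutieli step-up, valid under arbitrary
#' dependence between bins (adjacent spectral bins are strongly dependent):
#' on sorted p-values, `q(i) = min over j >= i of m * c(m) * p(j) / j`
#' capped at 1, with `c(m) = sum_{k=1..m} 1/k`. The plain
#' Benjamini-Hochberg variant (`c(m) = 1`) is available for sensitivity
#' analysis.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @param method `"BY"` (default) or `"BH"`.
#' @return q-values in the input order.
#' @export
adjust_by <- function(pvalues, method = c("BY", "BH")) {
  method <- match.arg(method)
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = method)
}

# test units: per-sample mean spectra (avoids pseudo-replication across the
# burns of one sample) or raw spectra
.test_units <- function(features, level = c("sample", "spectrum")) {
  level <- match.arg(level)
  if (level == "spectrum")
    return(list(x = features$x, class = features$meta$tissue_class,
                unit = features$meta$burn_id))
  sid <- features$meta$sample_id
  ux <- rowsum(features$x, sid)          # rows ordered by sort(unique(sid))
  ux <- ux / as.vector(table(sid)[rownames(ux)])
  cls <- vapply(rownames(ux), function(s)
    features$meta$tissue_class[match(s, sid)], character(1))
  list(x = ux, class = cls, unit = rownames(ux))
}

#' Rank tests for class-discriminatory bins
#'
#' Per bin, a Wilcoxon rank-sum test (two classes) or Kruskal-Wallis test
#' (more than two), both tie-corrected with the standard normal/chi-square
#' approximation, on the normalized intensities of the test units. Units
#' default to per-sample mean spectra. Bins constant across all units get
#' `P = 1` by convention. q-values come from [adjust_by()] over all bins;
#' the median log2 fold change is computed between `class_pair` with the
#' shared pseudo-count rule of [log2_fold_change()].
#'
#' @param features A `reims_features` object.
#' @param classes Class labels to compare (default: all present). Each
#'   named class must have at least 3 units at the chosen level.
#' @param level `"sample"` (default) or `"spectrum"`.
#' @param class_pair Two classes for the fold-change column (default: the
#'   first two of `classes`).
#' @param method FDR method passed to [adjust_by()].
#' @return data.frame of class `peak_tests`, one row per bin: `bin`
#'   (lower-edge label, Da), `test`, `p`, `q`, `log2fc`,
#'   `median.<class>` per class and `pooled_median` intensity.
#' @export
test_bins <- function(features, classes = NULL,
                      level = c("sample", "spectrum"), class_pair = NULL,
                      method = c("BY", "BH")) {
  stopifnot(inherits(features, "reims_features"))
  u <- .test_units(features, level)
  if (is.null(classes)) classes <- sort(unique(u$class))
  stopifnot(length(classes) >= 2)
  sel <- u$class %in% classes
  x <- u$x[sel, , drop = FALSE]
  g <- factor(u$class[sel], classes)
  if (any(table(g) < 3))
    stop("each class needs >= 3 units at level '",
         if (is.character(level)) level[1] else level, "'")
  if (is.null(class_pair)) class_pair <- classes[1:2]
  stopifnot(length(class_pair) == 2, all(class_pair %in% classes))
  two <- length(classes) == 2
  test_name <- if (two) "rank-sum" else "kruskal-wallis"
  eps <- {
    pos <- features$x[features$x > 0]
    if (length(pos)) min(pos) / 10 else 1e-12
  }
  n_bin <- ncol(x)
  p <- numeric(n_bin)
  ia <- g == class_pair[1]; ib <- g == class_pair[2]
  med <- matrix(NA_real_, n_bin, length(classes),
                dimnames = list(NULL, classes))
  for (cl in classes)
    med[, cl] <- apply(x[g == cl, , drop = FALSE], 2, stats::median)
  constant <- apply(x, 2, function(v) diff(range(v)) == 0)
  for (j in seq_len(n_bin)) {
    if (constant[j]) { p[j] <- 1; next }
    p[j] <- if (two)
      stats::wilcox.test(x[ia, j], x[ib, j], exact = FALSE)$p.value
    else
      stats::kruskal.test(x[, j], g)$p.value
  }
  if (any(constant))
    message(sum(constant), " constant bin(s) assigned P = 1")
  res <- data.frame(
    bin = features$grid$labels,
    test = ifelse(constant, "constant", test_name),
    p = p, q = adjust_by(p, method = match.arg(method)),
    log2fc = log2((med[, class_pair[1]] + eps) / (med[, class_pair[2]] + eps)),
    stringsAsFactors = FALSE)
  for (cl in classes) res[[paste0("median.", cl)]] <- med[, cl]
  res$pooled_median <- apply(x, 2, stats::median)
  class(res) <- c("peak_tests", "data.frame")
  res
}

#' Median-based log2 fold change for one bin
#'
#' `log2((median_a + eps) / (median_b + eps))` with pseudo-count
#' `eps = (smallest positive normalized intensity in the matrix) / 10`, so
#' zero medians give large but finite fold changes. Antisymmetric in the
#' two classes.
#'
#' @param features A `reims_features` object.
#' @param bin Bin label (lower edge, Da).
#' @param class_a,class_b Class labels.
#' @param level Test-unit level, see [test_bins()].
#' @return Signed log2 ratio.
#' @export
log2_fold_change <- function(features, bin, class_a, class_b,
                             level = c("sample", "spectrum")) {
  stopifnot(inherits(features, "reims_features"))
  j <- which(abs(features$grid$labels - bin) < features$grid$width / 2)
  if (length(j) != 1) stop("no unique bin labelled ", bin)
  u <- .test_units(features, level)
  for (cl in c(class_a, class_b))
    if (!cl %in% u$class) stop("class not present: ", cl)
  pos <- features$x[features$x > 0]
  eps <- if (length(pos)) min(pos) / 10 else 1e-12
  ma <- stats::median(u$x[u$class == class_a, j])
  mb <- stats::median(u$x[u$class == class_b, j])
  log2((ma + eps) / (mb + eps))
}

#' Shortlist the most significant and intense bins
#'
#' Filters to `p < p_max` and `q < q_max` (defaults 0.001/0.001), ranks the
#' survivors by descending pooled median intensity and returns the first
#' `n` — the "top ten most significant and intense peaks" selection used
#' for reporting discriminant lipids.
#'
#' @param results A `peak_tests` data.frame from [test_bins()].
#' @param n Shortlist length (default 10).
#' @param p_max,q_max Significance cutoffs.
#' @return The shortlisted rows, ranked; fewer than `n` survivors returns
#'   all of them with a warning.
#' @export
top_discriminant <- function(results, n = 10, p_max = 0.001, q_max = 0.001) {
  stopifnot(inherits(results, "data.frame"), n >= 1)
  keep <- results[results$p < p_max & results$q < q_max, , drop = FALSE]
  keep <- keep[order(-keep$pooled_median), , drop = FALSE]
  if (nrow(keep) < n)
    warning(sprintf("only %d bin(s) pass p < %g and q < %g", nrow(keep),
                    p_max, q_max))
  utils::head(keep, n)
}
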