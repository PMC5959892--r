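#' Fit the PCA stage of a recognition model
#'
#' Mean-centred principal component analysis (no scaling) of the feature
#' matrix via singular value decomposition. Loadings follow a fixed sign
#' convention (first element of non-negligible magnitude positive) so fits
#' are reproducible across platforms.
#'
#' @param x Numeric matrix, spectra x bins.
#' @param n_pcs Number of components to retain (default 25, the standard
#'   depth for whole-spectrum PC-LDA recognition models). Reduced with a
#'   warning when it exceeds the matrix rank.
#' @return Object of class `reims_pca`: `center`, orthonormal `loadings`
#'   (bins x k), `scores` (rows x k), `evar` (explained-variance fraction
#'   per retained PC) and `n_pcs`.
#' @export
fit_pca <- function(x, n_pcs = 25) {
  stopifnot(is.matrix(x), n_pcs >= 1)
  rank_max <- min(nrow(x) - 1L, ncol(x))
  if (nrow(x) < n_pcs + 1)
    rank_max <- min(rank_max, nrow(x) - 1L)
  if (n_pcs > rank_max) {
    warning(sprintf("n_pcs reduced from %d to matrix rank limit %d",
                    n_pcs, rank_max))
    n_pcs <- rank_max
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  load <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(load))) {     # sign convention
    nz <- which(abs(load[, j]) > 1e-12)[1]
    if (!is.na(nz) && load[nz, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  evar <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(center = pc$center, loadings = load, scores = scores,
                 evar = evar[seq_len(n_pcs)], n_pcs = n_pcs),
            class = "reims_pca")
}

#' Fit the linear-discriminant stage on PC scores
#'
#' Gaussian linear discriminant analysis: per-class means, pooled
#' within-class covariance with a small ridge for numerical stability, class
#' priors, and the discriminant axes (top eigenvectors of
#' `pooled_cov^-1 %*% between-class scatter`) used for 2D/3D score plots.
#'
#' @param scores Numeric matrix of PC scores, rows = spectra.
#' @param labels Class label per row.
#' @param ridge Ridge coefficient; `ridge * mean(diag(pooled_cov))` is added
#'   to the covariance diagonal. Default 1e-6 — needed because 25 PCs can
#'   approach the per-class row counts.
#' @param priors `"equal"` (default; class sizes reflect sample
#'   availability, not prevalence), `"proportional"`, or a named numeric
#'   vector summing to 1.
#' @return Object of class `reims_lda`: `classes`, `means` (classes x k),
#'   `cov` (pooled, ridged), `priors`, `ld_axes` (k x (classes - 1)).
#' @export
fit_lda <- function(scores, labels, ridge = 1e-6, priors = "equal") {
  stopifnot(is.matrix(scores), nrow(scores) == length(labels))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  counts <- table(factor(labels, classes))
  if (any(counts < 2))
    stop("class(es) with fewer than 2 rows: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  k <- ncol(scores)
  means <- t(vapply(classes, function(cl)
    colMeans(scores[labels == cl, , drop = FALSE]), numeric(k)))
  sw <- matrix(0, k, k)
  for (cl in classes) {
    xc <- sweep(scores[labels == cl, , drop = FALSE], 2, means[cl, ])
    sw <- sw + crossprod(xc)
  }
  sw <- sw / (nrow(scores) - length(classes))
  # ridge relative to the covariance scale; absolute floor keeps degenerate
  # (zero within-class variance) fits invertible
  ridge_abs <- ridge * mean(diag(sw))
  if (!is.finite(ridge_abs) || ridge_abs <= 0) ridge_abs <- 1e-10
  sw <- sw + diag(ridge_abs, k)
  pri <- if (identical(priors, "equal")) {
    stats::setNames(rep(1 / length(classes), length(classes)), classes)
  } else if (identical(priors, "proportional")) {
    stats::setNames(as.numeric(counts) / sum(counts), classes)
  } else {
    stopifnot(is.numeric(priors), setequal(names(priors), classes),
              abs(sum(priors) - 1) < 1e-8)
    priors[classes]
  }
  # discriminant axes via symmetric whitening of the between-class scatter
  gm <- colMeans(means)
  sb <- crossprod(sweep(means, 2, gm)) / (length(classes) - 1)
  es <- eigen(sw, symmetric = TRUE)
  wh <- es$vectors %*% diag(1 / sqrt(pmax(es$values, 1e-12)), k) %*% t(es$vectors)
  eb <- eigen(wh %*% sb %*% wh, symmetric = TRUE)
  n_ld <- min(length(classes) - 1L, k)
  ld <- wh %*% eb$vectors[, seq_len(n_ld), drop = FALSE]
  ld <- sweep(ld, 2, sqrt(colSums(ld^2)), "/")
  structure(list(classes = classes, means = means, cov = sw, priors = pri,
                 ld_axes = ld, counts = as.integer(counts)),
            class = "reims_lda")
}

#' Fit a PC-LDA recognition model
#'
#' Composes [fit_pca()] and [fit_lda()]: binned spectra are projected onto
#' the retained principal components and a Gaussian linear discriminant with
#' pooled covariance is fitted in that subspace. This whole-spectrum
#' "fingerprint" model is what the real-time recognition software evaluates
#' at each burn.
#'
#' @param features A `reims_features` object, or a numeric matrix with
#'   `labels` supplied.
#' @param labels Class labels (taken from `features$meta$tissue_class` when
#'   a `reims_features` is given).
#' @param n_pcs Retained principal components (default 25).
#' @param ridge,priors Passed to [fit_lda()].
#' @return Object of class `reims_pclda` combining both stages.
#' @export
fit_pclda <- function(features, labels = NULL, n_pcs = 25, ridge = 1e-6,
                      priors = "equal") {
  if (inherits(features, "reims_features")) {
    x <- features$x
    if (is.null(labels)) labels <- features$meta$tissue_class
  } else x <- features
  pca <- fit_pca(x, n_pcs)
  lda <- fit_lda(pca$scores, labels, ridge = ridge, priors = priors)
  structure(list(pca = pca, lda = lda, n_bins = ncol(x)),
            class = "reims_pclda")
}

#' @export
print.reims_pclda <- function(x, ...) {
  cat(sprintf("<reims_pclda> %d PCs (%.1f%% variance), classes: %s\n",
              x$pca$n_pcs, 100 * sum(x$pca$evar),
              paste(x$lda$classes, collapse = ", ")))
  invisible(x)
}

# log Gaussian density (up to a shared constant) in PC space; rows x classes
.pclda_logdens <- function(lda, z) {
  ci <- chol(lda$cov)
  out <- matrix(0, nrow(z), length(lda$classes),
                dimnames = list(NULL, lda$classes))
  for (cl in lda$classes) {
    d <- sweep(z, 2, lda$means[cl, ])
    out[, cl] <- -0.5 * colSums(backsolve(ci, t(d), transpose = TRUE)^2) +
      log(lda$priors[[cl]])
  }
  out
}

#' Classify spectra with a fitted PC-LDA model
#'
#' Projects each binned, normalized spectrum into the model's PC subspace
#' and evaluates Gaussian class posteriors with the pooled covariance. The
#' reliability of a call is the maximum posterior; calls below the
#' reliability threshold are flagged as not reported, mirroring real-time
#' recognition where sub-threshold classifications are ignored.
#'
#' @param object A `reims_pclda` model.
#' @param newdata Numeric matrix (spectra x bins, same grid as training), a
#'   single numeric vector, or a `reims_features` object.
#' @param threshold Reliability threshold in `(0, 1)`; default 0.75.
#' @param ... Unused.
#' @return data.frame with one row per spectrum: `burn_id` (when
#'   available), `predicted`, one `posterior.<class>` column per class,
#'   `reliability` and `reported`.
#' @export
predict.reims_pclda <- function(object, newdata, threshold = 0.75, ...) {
  ids <- NULL
  if (inherits(newdata, "reims_features")) {
    ids <- newdata$meta$burn_id
    newdata <- newdata$x
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_bins)
    stop(sprintf("spectrum has %d bins; model expects %d",
                 ncol(newdata), object$n_bins))
  z <- sweep(newdata, 2, object$pca$center) %*% object$pca$loadings
  ld <- .pclda_logdens(object$lda, z)      # rows x classes
  ld <- ld - apply(ld, 1, max)
  post <- exp(ld)
  post <- post / rowSums(post)
  pred <- object$lda$classes[apply(post, 1, which.max)]
  rel <- apply(post, 1, max)
  out <- data.frame(
    burn_id = if (is.null(ids)) rownames(newdata) %||% sprintf("row_%d", seq_len(nrow(newdata))) else ids,
    predicted = pred, stringsAsFactors = FALSE)
  for (cl in object$lda$classes) out[[paste0("posterior.", cl)]] <- post[, cl]
  out$reliability <- rel
  out$reported <- rel >= threshold
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
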