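#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement for nominal categories:
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the
#' product of the marginal proportions. Significance uses the standard
#' null-hypothesis asymptotic standard error computed from the marginals
#' (Cohen 1960 / Fleiss), `z = kappa / SE0`, with a two-sided normal
#' p-value. Unweighted: tissue classes are nominal.
#'
#' @param ratings_a,ratings_b Equal-length label vectors (one entry per
#'   rated site), sharing a label set.
#' @return Object of class `kappa_result`: `kappa`, `p_o`, `p_e`, `se0`,
#'   `z`, `p_value`, `band` (verbal agreement band, see [kappa_band()]),
#'   `n` and the cross-tabulation `table`.
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  stopifnot(length(ratings_a) == length(ratings_b), length(ratings_a) >= 2)
  lev <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  tab <- table(factor(ratings_a, lev), factor(ratings_b, lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  pi_ <- rowSums(tab) / n
  qi_ <- colSums(tab) / n
  p_e <- sum(pi_ * qi_)
  if (1 - p_e < 1e-12) {
    if (p_o == 1) {
      k <- 1; se0 <- NA_real_; z <- NA_real_; pv <- NA_real_
    } else stop("degenerate marginals: expected agreement is 1 but raters differ")
  } else {
    k <- (p_o - p_e) / (1 - p_e)
    se0 <- sqrt(p_e + p_e^2 - sum(pi_ * qi_ * (pi_ + qi_))) /
      ((1 - p_e) * sqrt(n))
    z <- k / se0
    pv <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(kappa = k, p_o = p_o, p_e = p_e, se0 = se0, z = z,
                 p_value = pv, band = suppressWarnings(kappa_band(k)),
                 n = n, table = tab),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s), z = %.3g, P = %.3g, n = %d\n",
              x$kappa, x$band, x$z, x$p_value, x$n))
  invisible(x)
}

#' Verbal agreement band for a kappa coefficient
#'
#' Conventional bands: 0 no agreement, (0, 0.20] poor, (0.20, 0.40] fair,
#' (0.40, 0.60] moderate, (0.60, 0.80] good, > 0.80 very good. The upper
#' closure of "good" at 0.80 leaves no gap below the "very good" examples
#' quoted at 0.81 and above. Negative kappa (worse than chance) maps to
#' "no agreement" with a warning.
#'
#' @param kappa Coefficient in `[-1, 1]`.
#' @return Band label, character.
#' @export
kappa_band <- function(kappa) {
  stopifnot(is.numeric(kappa), length(kappa) == 1, kappa >= -1, kappa <= 1)
  if (kappa < 0) {
    warning("negative kappa: agreement worse than chance")
    return("no agreement")
  }
  eps <- 1e-9  # absorb float dust at band edges (e.g. 40/50 arithmetic)
  if (kappa == 0) "no agreement"
  else if (kappa <= 0.20 + eps) "poor"
  else if (kappa <= 0.40 + eps) "fair"
  else if (kappa <= 0.60 + eps) "moderate"
  else if (kappa <= 0.80 + eps) "good"
  else "very good"
}

#' Pairwise kappa between several raters
#'
#' Convenience wrapper applying [cohens_kappa()] to every pair of columns
#' of a per-site rating table (e.g. surgeon, recognition model,
#' histopathologist).
#'
#' @param ratings data.frame or matrix; one row per rated site, one column
#'   per rater.
#' @return data.frame with one row per rater pair: kappa, z, p-value, band.
#' @export
rater_agreement <- function(ratings) {
  ratings <- as.data.frame(ratings)
  stopifnot(ncol(ratings) >= 2)
  prs <- utils::combn(names(ratings), 2, simplify = FALSE)
  do.call(rbind, lapply(prs, function(pr) {
    k <- cohens_kappa(ratings[[pr[1]]], ratings[[pr[2]]])
    data.frame(rater_a = pr[1], rater_b = pr[2], kappa = k$kappa, z = k$z,
               p_value = k$p_value, band = k$band, stringsAsFactors = FALSE)
  }))
}
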