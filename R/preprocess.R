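#' Define the m/z binning grid
#'
#' Spectra are analysed in a fixed window and accumulated into equal-width
#' bins. Bins are left-closed, right-open intervals
#' `[lower + i*width, lower + (i+1)*width)` and are labelled by their lower
#' edge, so no peak can be counted twice. Defaults reproduce the standard
#' analysis window of 600-1000 m/z at 0.1 Da, i.e. 4000 bins.
#'
#' @param lower Lower edge of the analysis window (Da).
#' @param upper Upper edge of the analysis window (Da, exclusive).
#' @param width Bin width (Da); `(upper - lower) / width` must be integral.
#' @return An object of class `bin_grid`.
#' @export
bin_grid <- function(lower = 600, upper = 1000, width = 0.1) {
  stopifnot(upper > lower, width > 0)
  n <- (upper - lower) / width
  if (abs(n - round(n)) > 1e-9)
    stop("(upper - lower) / width must be an exact integer")
  n <- as.integer(round(n))
  structure(list(lower = lower, upper = upper, width = width, n_bins = n,
                 labels = round(lower + (seq_len(n) - 1L) * width, 6)),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> [%g, %g) Da, width %g: %d bins\n",
              x$lower, x$upper, x$width, x$n_bins))
  invisible(x)
}

# Bin index for each m/z (NA outside the window). Edge membership is decided
# with a 1e-6 bin-width snap so that values printed at the bin edge
# (e.g. 700.1) land in the bin they label despite float representation.
bin_index <- function(mz, grid) {
  q <- (mz - grid$lower) / grid$width
  idx <- floor(q + 1e-6) + 1L
  idx[idx < 1L | idx > grid$n_bins] <- NA_integer_
  idx
}

#' Correct spectrum-wide mass-calibration drift against a lock mass
#'
#' Locates the most intense peak within `reference +/- search_window` and
#' subtracts the observed offset from every m/z in the spectrum (a constant,
#' single-point correction; drift on time-of-flight REIMS instruments is
#' well below 0.1 Da, so a ppm-proportional model is unnecessary). If no
#' peak lies in the search window the spectrum is returned unchanged with a
#' warning. The applied shift is stored in the `lock_shift` field.
#'
#' @param spectrum A `reims_spectrum`.
#' @param reference Lock mass (Da); the default 699.497 is the
#'   phospholipid ion conventionally used as internal lock mass for frozen
#'   tissue work (leucine enkephalin, 554.2615, serves as the external lock
#'   mass for fresh tissue).
#' @param search_window Half-width of the search window (Da).
#' @return The corrected `reims_spectrum`, with `lock_shift` set to the
#'   subtracted offset (0 when no lock peak was found).
#' @export
lock_mass_correct <- function(spectrum, reference = 699.497,
                              search_window = 0.3) {
  stopifnot(inherits(spectrum, "reims_spectrum"), search_window > 0)
  p <- spectrum$peaks
  cand <- which(abs(p$mz - reference) <= search_window)
  if (!length(cand)) {
    warning(sprintf("burn %s: no lock-mass peak within %.4g +/- %.3g Da",
                    spectrum$burn_id, reference, search_window))
    spectrum$lock_shift <- 0
    return(spectrum)
  }
  shift <- p$mz[cand[which.max(p$intensity[cand])]] - reference
  spectrum$peaks$mz <- p$mz - shift
  spectrum$lock_shift <- shift
  spectrum
}

#' Subtract a low-quantile baseline from a spectrum
#'
#' Chemical background in diathermy aerosol spectra is modelled as a flat
#' per-spectrum baseline estimated as a low quantile of the peak
#' intensities. The baseline is subtracted from every peak, results are
#' clipped at zero, and zero-intensity peaks are dropped.
#'
#' @param spectrum A `reims_spectrum`.
#' @param quantile Baseline quantile in `[0, 1)`; default 0.05.
#' @return The background-subtracted `reims_spectrum`.
#' @export
subtract_background <- function(spectrum, quantile = 0.05) {
  stopifnot(inherits(spectrum, "reims_spectrum"),
            quantile >= 0, quantile < 1)
  p <- spectrum$peaks
  if (!nrow(p)) return(spectrum)
  baseline <- stats::quantile(p$intensity, probs = quantile, names = FALSE)
  int <- pmax(p$intensity - baseline, 0)
  keep <- int > 0
  spectrum$peaks <- data.frame(mz = p$mz[keep], intensity = int[keep])
  spectrum
}

#' Accumulate a spectrum onto a bin grid
#'
#' Each peak's intensity is added to the bin containing its m/z; peaks
#' outside the window are discarded. Binning conserves total in-window
#' intensity exactly.
#'
#' @param spectrum A `reims_spectrum`.
#' @param grid A [bin_grid()].
#' @return Numeric vector of length `grid$n_bins`, named by bin lower edge.
#' @export
bin_spectrum <- function(spectrum, grid = bin_grid()) {
  stopifnot(inherits(spectrum, "reims_spectrum"), inherits(grid, "bin_grid"))
  v <- numeric(grid$n_bins)
  idx <- bin_index(spectrum$peaks$mz, grid)
  keep <- !is.na(idx)
  if (any(keep)) {
    acc <- rowsum(spectrum$peaks$intensity[keep], idx[keep])
    v[as.integer(rownames(acc))] <- acc[, 1]
  }
  names(v) <- sprintf("%.1f", grid$labels)
  v
}

#' Total-ion-current normalization of a binned spectrum
#'
#' Divides a binned intensity vector by its sum so rows are comparable
#' across burns. Vectors whose raw total falls below the signal floor are
#' flagged as QC rejects (no interpretable signal) instead of normalized.
#'
#' @param x Non-negative numeric vector of binned intensities.
#' @param signal_floor Minimum raw total signal; totals below it (or zero)
#'   are rejected. Default 0 rejects only all-zero vectors; the cohort
#'   pipeline uses 10 raw counts.
#' @return A list with `values` (normalized vector summing to 1, or `NULL`
#'   when rejected), `total` (raw sum) and `rejected` (logical).
#' @export
normalize_tic <- function(x, signal_floor = 0) {
  stopifnot(is.numeric(x))
  if (any(x < 0)) stop("binned intensities must be non-negative")
  s <- sum(x)
  rejected <- (s <= 0) || (s < signal_floor)
  list(values = if (rejected) NULL else x / s, total = s, rejected = rejected)
}

#' Build the binned, normalized feature matrix for a cohort
#'
#' Applies, per spectrum: lock-mass correction, low-quantile background
#' subtraction, binning onto the grid, and total-ion-current normalization.
#' Spectra failing the signal-floor QC are excluded and logged in the
#' `dropped` table.
#'
#' @param cohort A `reims_cohort`.
#' @param grid A [bin_grid()].
#' @param lockmass Lock mass (Da) passed to [lock_mass_correct()], or `NA`
#'   to skip the correction.
#' @param lock_window Lock-mass search half-window (Da).
#' @param background_quantile Baseline quantile for [subtract_background()];
#'   0 disables removal of sub-baseline peaks only when the low tail is empty.
#' @param signal_floor Minimum raw in-window intensity for a spectrum to be
#'   retained (counts).
#' @return An object of class `reims_features`: list with `x` (matrix,
#'   spectra x bins, rows named by burn id), `meta` (per-row metadata with
#'   applied lock shifts), `grid`, `normalization = "tic"` and `dropped`.
#' @export
build_feature_matrix <- function(cohort, grid = bin_grid(), lockmass = 699.497,
                                 lock_window = 0.3, background_quantile = 0.05,
                                 signal_floor = 10) {
  stopifnot(inherits(cohort, "reims_cohort"))
  if (!length(cohort)) stop("empty cohort")
  rows <- vector("list", length(cohort))
  meta <- cohort_meta(cohort)
  meta$lock_shift <- NA_real_
  keep <- logical(length(cohort))
  dropped <- list()
  for (i in seq_along(cohort$spectra)) {
    s <- cohort$spectra[[i]]
    if (!is.na(lockmass)) {
      s <- withCallingHandlers(
        lock_mass_correct(s, lockmass, lock_window),
        warning = function(w) invokeRestart("muffleWarning"))
      meta$lock_shift[i] <- s$lock_shift
    }
    s <- subtract_background(s, background_quantile)
    v <- bin_spectrum(s, grid)
    nt <- normalize_tic(v, signal_floor = signal_floor)
    if (nt$rejected) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(burn_id = s$burn_id, reason = "below signal floor",
                   raw_total = nt$total, stringsAsFactors = FALSE)
      next
    }
    rows[[i]] <- nt$values
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("all spectra rejected by QC")
  x <- do.call(rbind, rows[keep])
  rownames(x) <- meta$burn_id[keep]
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(burn_id = character(), reason = character(),
               raw_total = numeric(), stringsAsFactors = FALSE)
  if (nrow(dropped))
    message("QC-rejected spectra: ", paste(dropped$burn_id, collapse = ", "))
  structure(list(x = x, meta = meta[keep, , drop = FALSE], grid = grid,
                 normalization = "tic", dropped = dropped),
            class = "reims_features")
}

#' @export
print.reims_features <- function(x, ...) {
  cat(sprintf("<reims_features> %d spectra x %d bins (%s-normalized), %d QC-dropped\n",
              nrow(x$x), ncol(x$x), x$normalization, nrow(x$dropped)))
  invisible(x)
}

#' Export a feature matrix as CSV
#'
#' Rows are burns; the leading columns carry the metadata, followed by one
#' column per bin labelled by its lower edge.
#'
#' @param features A `reims_features` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(features, path) {
  stopifnot(inherits(features, "reims_features"))
  df <- cbind(features$meta, as.data.frame(features$x, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
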