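#' Construct a single-burn spectrum record
#'
#' The atomic observation of the pipeline: one centroided peak list produced
#' by a single diathermy burn, together with its clinical and acquisition
#' metadata. Peaks are stored sorted by m/z; exact duplicate m/z values are
#' merged by summing their intensities.
#'
#' @param mz Numeric vector of peak m/z values (Da).
#' @param intensity Numeric vector of peak intensities (counts, >= 0).
#' @param burn_id Unique identifier of the burn (sampling point).
#' @param sample_id Identifier of the tissue sample the burn belongs to.
#' @param patient_id Identifier of the patient the sample came from.
#' @param tissue_class Tissue class label, or `"unknown"` for blind spectra.
#' @param mode Acquisition mode, `"cut"` or `"coagulation"`.
#' @param tumour_content Percent viable tumour reported by histopathology
#'   for the sample, in `[0, 100]`, or `NA` when not assessed.
#' @return An object of class `reims_spectrum`.
#' @export
reims_spectrum <- function(mz, intensity, burn_id,
                           sample_id = burn_id, patient_id = sample_id,
                           tissue_class = "unknown", mode = "cut",
                           tumour_content = NA_real_) {
  stopifnot(is.numeric(mz), is.numeric(intensity), length(mz) == length(intensity))
  if (length(intensity) && (any(!is.finite(intensity)) || any(intensity < 0)))
    stop("intensities must be finite and non-negative")
  if (length(mz) && any(!is.finite(mz)))
    stop("m/z values must be finite")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(list(
    peaks = data.frame(mz = mz, intensity = intensity),
    burn_id = as.character(burn_id),
    sample_id = as.character(sample_id),
    patient_id = as.character(patient_id),
    tissue_class = as.character(tissue_class),
    mode = as.character(mode),
    tumour_content = as.numeric(tumour_content)
  ), class = "reims_spectrum")
}

#' @export
print.reims_spectrum <- function(x, ...) {
  cat(sprintf("<reims_spectrum> burn %s (%s/%s), class '%s', %d peaks\n",
              x$burn_id, x$patient_id, x$sample_id, x$tissue_class,
              nrow(x$peaks)))
  invisible(x)
}

#' Construct a cohort of spectra
#'
#' A cohort is an ordered collection of [reims_spectrum()] records with
#' unique burn ids, plus free-form provenance.
#'
#' @param spectra List of `reims_spectrum` objects.
#' @param provenance Optional character note on where the records came from.
#' @return An object of class `reims_cohort`.
#' @export
reims_cohort <- function(spectra, provenance = NA_character_) {
  stopifnot(is.list(spectra))
  if (!all(vapply(spectra, inherits, logical(1), "reims_spectrum")))
    stop("all elements must be reims_spectrum objects")
  ids <- vapply(spectra, `[[`, character(1), "burn_id")
  if (anyDuplicated(ids))
    stop("duplicate burn ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(spectra = spectra, provenance = provenance),
            class = "reims_cohort")
}

#' @export
length.reims_cohort <- function(x) length(x$spectra)

#' @export
`[.reims_cohort` <- function(x, i) reims_cohort(x$spectra[i], x$provenance)

#' @export
print.reims_cohort <- function(x, ...) {
  m <- cohort_meta(x)
  cat(sprintf("<reims_cohort> %d spectra, %d samples, %d patients\n",
              nrow(m), length(unique(m$sample_id)), length(unique(m$patient_id))))
  if (nrow(m)) print(table(m$tissue_class))
  invisible(x)
}

#' Metadata table of a cohort
#'
#' @param cohort A `reims_cohort`.
#' @return A data.frame with one row per spectrum: burn, sample and patient
#'   ids, tissue class, acquisition mode and tumour content.
#' @export
cohort_meta <- function(cohort) {
  stopifnot(inherits(cohort, "reims_cohort"))
  do.call(rbind, lapply(cohort$spectra, function(s)
    data.frame(burn_id = s$burn_id, sample_id = s$sample_id,
               patient_id = s$patient_id, tissue_class = s$tissue_class,
               mode = s$mode, tumour_content = s$tumour_content,
               stringsAsFactors = FALSE)))
}

.meta_cols <- c("burn_id", "patient_id", "sample_id", "tissue_class",
                "mode", "tumour_content")

#' Write a cohort as peak-list and metadata CSV files
#'
#' The exchange format is a long-form peak CSV (`burn_id, mz, intensity`)
#' plus a metadata CSV keyed by `burn_id`. Comma-separated, header row,
#' UTF-8, '.' decimal separator.
#'
#' @param cohort A `reims_cohort`.
#' @param peaks_path Path of the peak-list CSV to write.
#' @param meta_path Path of the metadata CSV to write.
#' @return Invisibly, the two paths.
#' @export
write_peaklists <- function(cohort, peaks_path, meta_path) {
  stopifnot(inherits(cohort, "reims_cohort"))
  pk <- do.call(rbind, lapply(cohort$spectra, function(s) {
    if (!nrow(s$peaks)) return(NULL)
    data.frame(burn_id = s$burn_id, mz = s$peaks$mz,
               intensity = s$peaks$intensity, stringsAsFactors = FALSE)
  }))
  if (is.null(pk))
    pk <- data.frame(burn_id = character(), mz = numeric(), intensity = numeric())
  utils::write.csv(pk, peaks_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort_meta(cohort)[, .meta_cols], meta_path,
                   row.names = FALSE, quote = FALSE)
  invisible(c(peaks_path, meta_path))
}

#' Read a cohort from peak-list and metadata CSV files
#'
#' Inverse of [write_peaklists()]. Every burn in the peak file must have a
#' metadata row; unknown columns in either file are rejected.
#'
#' @param peaks_path Peak-list CSV (`burn_id, mz, intensity`).
#' @param meta_path Metadata CSV keyed by `burn_id`.
#' @return A `reims_cohort`.
#' @export
read_peaklists <- function(peaks_path, meta_path) {
  if (!file.exists(peaks_path)) stop("peak file not found: ", peaks_path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  pk <- utils::read.csv(peaks_path, colClasses = "character",
                        stringsAsFactors = FALSE)
  want_pk <- c("burn_id", "mz", "intensity")
  if (!setequal(names(pk), want_pk)) {
    bad <- setdiff(names(pk), want_pk)
    if (length(bad)) stop("unknown peak-file columns: ", paste(bad, collapse = ", "))
    stop("peak file missing columns: ",
         paste(setdiff(want_pk, names(pk)), collapse = ", "))
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                          colClasses = c(tumour_content = "numeric"))
  if (!setequal(names(meta), .meta_cols)) {
    bad <- setdiff(names(meta), .meta_cols)
    if (length(bad)) stop("unknown metadata columns: ", paste(bad, collapse = ", "))
    stop("metadata missing columns: ",
         paste(setdiff(.meta_cols, names(meta)), collapse = ", "))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(pk[[col]]))
    bad <- which(is.na(v) & !is.na(pk[[col]]))
    if (length(bad))  # +1 for the header line of the file
      stop(sprintf("non-numeric %s value at line %d of %s", col, bad[1] + 1L,
                   peaks_path))
    v
  }
  mz <- num("mz"); int <- num("intensity")
  burns <- unique(pk$burn_id)
  missing_meta <- setdiff(burns, meta$burn_id)
  if (length(missing_meta))
    stop("no metadata for burn(s): ", paste(missing_meta, collapse = ", "))
  specs <- lapply(burns, function(b) {
    sel <- pk$burn_id == b
    m <- meta[match(b, meta$burn_id), ]
    reims_spectrum(mz[sel], int[sel], burn_id = b, sample_id = m$sample_id,
                   patient_id = m$patient_id, tissue_class = m$tissue_class,
                   mode = m$mode, tumour_content = m$tumour_content)
  })
  reims_cohort(specs, provenance = peaks_path)
}

#' Read centroided spectra from an mzML file
#'
#' Convenience reader for the community-standard mzML 1.1 format (via the
#' `mzR` package). The file must contain centroided scans; metadata beyond
#' a synthesized scan id is not populated.
#'
#' @param path Path to an mzML file.
#' @return A `reims_cohort` with one record per scan, burn ids
#'   `scan_1, scan_2, ...` in scan order and tissue class `"unknown"`.
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  if (!file.exists(path)) stop("file not found: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  if (any(!hd$centroided, na.rm = TRUE) || any(is.na(hd$centroided)))
    stop("profile-mode (or unlabelled) scans found: centroid the data first")
  specs <- lapply(seq_len(nrow(hd)), function(i) {
    p <- mzR::peaks(fh, i)
    reims_spectrum(p[, 1], p[, 2], burn_id = sprintf("scan_%d", i))
  })
  reims_cohort(specs, provenance = path)
}
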