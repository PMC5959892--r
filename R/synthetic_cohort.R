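#' Define a lipid peak template for cohort simulation
#'
#' A template is one lipid-derived peak the simulator places in every
#' spectrum: a fixed m/z centre, a base intensity, and per-class
#' multiplicative fold changes. A fold change of 1 in every class makes the
#' peak non-discriminant.
#'
#' @param mz Peak centre (Da); must lie inside the analysis window
#'   `[600, 1000)`.
#' @param base_intensity Base intensity (arbitrary counts, > 0).
#' @param fold Named numeric vector of per-class fold changes (> 0);
#'   classes not named default to 1.
#' @return An object of class `lipid_template`.
#' @export
lipid_template <- function(mz, base_intensity, fold = numeric()) {
  stopifnot(is.numeric(mz), length(mz) == 1, is.finite(mz),
            is.numeric(base_intensity), base_intensity > 0)
  if (mz < 600 || mz >= 1000)
    stop(sprintf("template m/z %.4f outside the analysis window [600, 1000)", mz))
  if (length(fold)) {
    stopifnot(!is.null(names(fold)), all(nzchar(names(fold))), all(fold > 0))
  }
  structure(list(mz = mz, base_intensity = base_intensity, fold = fold),
            class = "lipid_template")
}

#' Default lipid templates of the simulated cohort
#'
#' Twenty peak templates spanning the phospholipid-dominated 600-1000 m/z
#' region. Five are discriminant, placed at the masses reported to drive
#' tissue-class separation in gynaecological REIMS profiles (673.481,
#' 685.517, 699.497, 742.539, 744.555): the cancer class is elevated
#' four-fold at 673.481/685.517, borderline tumours sit intermediate at
#' 699.497/742.539 and are elevated at 744.555, so all three classes are
#' mutually separable. The 699.497 and 744.555 peaks carry the highest base
#' intensities, mirroring their dominance in both normal and malignant
#' tissue, and 699.497 doubles as the internal lock mass.
#'
#' @param classes Class labels the fold changes refer to.
#' @return A list of [lipid_template()] objects.
#' @export
default_lipid_templates <- function(classes = c("normal", "borderline", "cancer")) {
  stopifnot(length(classes) == 3)
  b <- classes[2]; ca <- classes[3]
  disc <- list(
    lipid_template(673.481, 300,  stats::setNames(4, ca)),
    lipid_template(685.517, 200,  stats::setNames(4, ca)),
    lipid_template(699.497, 1000, stats::setNames(c(2, 4), c(b, ca))),
    lipid_template(742.539, 400,  stats::setNames(c(2, 4), c(b, ca))),
    lipid_template(744.555, 800,  stats::setNames(4, b))
  )
  flat_mz <- c(619.34, 627.53, 655.46, 671.47, 687.54, 701.51, 715.48,
               723.50, 747.52, 750.54, 766.54, 773.53, 788.61, 810.60, 834.53)
  flat_base <- c(150, 90, 220, 130, 60, 180, 75, 250, 110, 95,
                 320, 140, 85, 200, 120)
  c(disc, Map(lipid_template, flat_mz, flat_base))
}

#' Configure a synthetic REIMS cohort
#'
#' Fixes the full study design of a simulation: class structure, cohort
#' sizes, lipid templates, noise magnitudes, chemical background,
#' calibration drift and the random seed. The defaults are the package's
#' reference scenario: 3 tissue classes x 10 patients x 2 samples x 3
#' burns, five discriminant lipids at fold change 4, patient effect SD 0.2
#' and burn noise SD 0.1 on the log-intensity scale, and calibration drift
#' SD 0.02 Da correctable via the 699.497 lock mass.
#'
#' @param classes Character vector of tissue-class labels.
#' @param patients_per_class Patients simulated per class.
#' @param samples_per_patient Tissue samples per patient.
#' @param burns_per_sample Burns (spectra) per sample.
#' @param templates List of [lipid_template()] objects.
#' @param patient_sd SD of the shared per-patient log-intensity offset.
#' @param burn_sd SD of the per-burn, per-peak log-intensity noise.
#' @param background_amplitude Mean intensity of background peaks; default
#'   1% of the median template base intensity.
#' @param n_background Background peaks drawn per spectrum.
#' @param drift_sd SD of the per-spectrum constant m/z calibration drift (Da).
#' @param lock_mass Lock-mass m/z (Da); a template must sit at this mass so
#'   every spectrum carries a lock peak.
#' @param seed Integer random seed; generation is byte-reproducible under it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(classes = c("normal", "borderline", "cancer"),
                             patients_per_class = 10,
                             samples_per_patient = 2,
                             burns_per_sample = 3,
                             templates = default_lipid_templates(classes),
                             patient_sd = 0.2,
                             burn_sd = 0.1,
                             background_amplitude = NULL,
                             n_background = 50,
                             drift_sd = 0.02,
                             lock_mass = 699.497,
                             seed) {
  if (missing(seed)) stop("a random seed is mandatory")
  stopifnot(length(classes) >= 1, !anyDuplicated(classes),
            patients_per_class >= 1, samples_per_patient >= 1,
            burns_per_sample >= 1,
            patient_sd >= 0, burn_sd >= 0, drift_sd >= 0, n_background >= 0)
  if (!all(vapply(templates, inherits, logical(1), "lipid_template")))
    stop("templates must be lipid_template objects")
  for (t in templates) {
    unknown <- setdiff(names(t$fold), classes)
    if (length(unknown))
      stop("template fold change names unknown class(es): ",
           paste(unknown, collapse = ", "))
  }
  base <- vapply(templates, `[[`, numeric(1), "base_intensity")
  if (is.null(background_amplitude))
    background_amplitude <- 0.01 * stats::median(base)
  stopifnot(background_amplitude >= 0)
  tmz <- vapply(templates, `[[`, numeric(1), "mz")
  if (!any(abs(tmz - lock_mass) < 1e-6))
    warning("no template at the lock mass: simulated spectra will lack a lock peak")
  structure(list(classes = classes, patients_per_class = patients_per_class,
                 samples_per_patient = samples_per_patient,
                 burns_per_sample = burns_per_sample, templates = templates,
                 patient_sd = patient_sd, burn_sd = burn_sd,
                 background_amplitude = background_amplitude,
                 n_background = as.integer(n_background),
                 drift_sd = drift_sd, lock_mass = lock_mass,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# fold-change matrix: templates x classes, default 1
fold_matrix <- function(config) {
  m <- matrix(1, nrow = length(config$templates), ncol = length(config$classes),
              dimnames = list(NULL, config$classes))
  for (i in seq_along(config$templates)) {
    f <- config$templates[[i]]$fold
    if (length(f)) m[i, names(f)] <- f
  }
  m
}

#' Generate a synthetic REIMS cohort
#'
#' Draws one spectrum per burn under a multiplicative log-normal intensity
#' model: the intensity of template `t` in class `c` is
#' `base(t) * fold(t, c) * exp(patient effect) * exp(burn noise)`, with one
#' shared patient offset per patient (creating the within-patient
#' correlation that makes leave-one-patient-out validation strictly harder
#' than spectrum-level validation) and i.i.d. per-peak burn noise. Each
#' spectrum additionally carries low-amplitude background peaks at uniform
#' random m/z, and every m/z — lipid peaks, lock mass and background alike —
#' is shifted by a per-spectrum calibration drift drawn from
#' `N(0, drift_sd)`, so lock-mass correction can undo it exactly.
#' Cancer-class samples are given 100% tumour content so none is lost to
#' the tumour-content filter by construction.
#'
#' @param config A [synthetic_config()].
#' @return A `reims_cohort` of
#'   `classes x patients x samples x burns` spectra.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  tmz <- vapply(config$templates, `[[`, numeric(1), "mz")
  base <- vapply(config$templates, `[[`, numeric(1), "base_intensity")
  fm <- fold_matrix(config)
  specs <- list()
  for (cls in config$classes) {
    for (p in seq_len(config$patients_per_class)) {
      pid <- sprintf("%s_P%02d", cls, p)
      p_eff <- stats::rnorm(1, 0, config$patient_sd)
      for (s in seq_len(config$samples_per_patient)) {
        sid <- sprintf("%s_S%d", pid, s)
        for (b in seq_len(config$burns_per_sample)) {
          bid <- sprintf("%s_B%d", sid, b)
          int <- base * fm[, cls] * exp(p_eff) *
            exp(stats::rnorm(length(base), 0, config$burn_sd))
          mz <- tmz
          if (config$n_background > 0 && config$background_amplitude > 0) {
            bg_mz <- stats::runif(config$n_background, 600, 1000)
            bg_int <- stats::rexp(config$n_background,
                                  rate = 1 / config$background_amplitude)
            mz <- c(mz, bg_mz); int <- c(int, bg_int)
          }
          drift <- stats::rnorm(1, 0, config$drift_sd)
          specs[[length(specs) + 1L]] <- reims_spectrum(
            mz + drift, int, burn_id = bid, sample_id = sid, patient_id = pid,
            tissue_class = cls, mode = "cut",
            tumour_content = if (cls == "cancer") 100 else NA_real_)
        }
      }
    }
  }
  reims_cohort(specs, provenance = sprintf("synthetic cohort, seed %d", config$seed))
}

#' Ground-truth log2 fold changes of a simulation scenario
#'
#' For every template, the expected log2 fold change between two named
#' classes, plus the 0.1 Da bin its m/z falls into — the reference against
#' which univariate discovery is validated.
#'
#' @param config A [synthetic_config()].
#' @param class_a,class_b Class labels; the fold change is
#'   `log2(fold(t, class_a) / fold(t, class_b))`.
#' @param grid [bin_grid()] used to map template m/z to bin labels.
#' @return data.frame with columns `mz`, `bin` (lower-edge label),
#'   `log2fc` and `discriminant` (logical, `log2fc != 0`).
#' @export
ground_truth <- function(config, class_a, class_b, grid = bin_grid()) {
  stopifnot(inherits(config, "synthetic_config"))
  for (cl in c(class_a, class_b))
    if (!cl %in% config$classes) stop("unknown class label: ", cl)
  fm <- fold_matrix(config)
  tmz <- vapply(config$templates, `[[`, numeric(1), "mz")
  idx <- bin_index(tmz, grid)
  data.frame(mz = tmz, bin = grid$labels[idx],
             log2fc = log2(fm[, class_a] / fm[, class_b]),
             discriminant = fm[, class_a] != fm[, class_b])
}
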