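# Shared fixtures, all generated in code.

.reims_test_cache <- new.env(parent = emptyenv())

# Reference simulation scenario (package defaults), memoised across files.
default_scenario <- function(seed = 1) {
  key <- sprintf("scenario_%d", seed)
  if (!exists(key, .reims_test_cache)) {
    cfg <- synthetic_config(seed = seed)
    cohort <- generate_cohort(cfg)
    fm <- suppressMessages(build_feature_matrix(cohort))
    assign(key, list(config = cfg, cohort = cohort, features = fm),
           .reims_test_cache)
  }
  get(key, .reims_test_cache)
}

# Small two-class template set: lock-mass peak plus two discriminant and
# three flat lipid peaks.
two_class_templates <- function(fold = 4) {
  list(
    lipid_template(699.497, 1000),
    lipid_template(673.481, 300, c(cancer = fold)),
    lipid_template(744.555, 500, c(cancer = fold)),
    lipid_template(655.46, 200),
    lipid_template(723.50, 150),
    lipid_template(810.60, 100)
  )
}

two_class_config <- function(seed, fold = 4, patients = 4, samples = 1,
                             burns = 2, patient_sd = 0, burn_sd = 0,
                             background = 0, n_background = 0, drift_sd = 0) {
  synthetic_config(classes = c("normal", "cancer"),
                   patients_per_class = patients,
                   samples_per_patient = samples, burns_per_sample = burns,
                   templates = two_class_templates(fold),
                   patient_sd = patient_sd, burn_sd = burn_sd,
                   background_amplitude = background,
                   n_background = n_background,
                   drift_sd = drift_sd, seed = seed)
}

# All fold changes 1: a pure-null cohort for FDR calibration checks.
null_config <- function(seed, patients = 4, burns = 2, burn_sd = 0.3) {
  synthetic_config(classes = c("normal", "cancer"),
                   patients_per_class = patients, samples_per_patient = 1,
                   burns_per_sample = burns,
                   templates = lapply(seq(610, 990, by = 20), function(m)
                     lipid_template(m, 100 + (m %% 7) * 30)),
                   patient_sd = 0.1, burn_sd = burn_sd,
                   background_amplitude = 1, n_background = 20,
                   drift_sd = 0, lock_mass = 610, seed = seed)
}

# Minimal mzML 1.1 writer for fixtures (64-bit little-endian, uncompressed).
write_test_mzml <- function(path, peaklists, centroided = TRUE) {
  enc <- function(x)
    jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                  endian = "little"))
  mode_acc <- if (centroided) "MS:1000127" else "MS:1000128"
  mode_name <- if (centroided) "centroid spectrum" else "profile spectrum"
  spec_xml <- vapply(seq_along(peaklists), function(i) {
    p <- peaklists[[i]]
    emz <- enc(p$mz); eint <- enc(p$intensity)
    paste0(
      sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
              i - 1L, i, length(p$mz)),
      sprintf('<cvParam cvRef="MS" accession="%s" name="%s" value=""/>',
              mode_acc, mode_name),
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
      '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>',
      '<binaryDataArrayList count="2">',
      sprintf('<binaryDataArray encodedLength="%d">', nchar(emz)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      sprintf('<binary>%s</binary></binaryDataArray>', emz),
      sprintf('<binaryDataArray encodedLength="%d">', nchar(eint)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      sprintf('<binary>%s</binary></binaryDataArray>', eint),
      '</binaryDataArrayList></spectrum>')
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '</fileContent></fileDescription>',
    '<run id="run1">',
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp1">',
            length(peaklists)),
    paste0(spec_xml, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(xml, path)
  invisible(path)
}
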