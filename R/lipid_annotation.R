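# Monoisotopic atomic masses (Da) and ion-mass bookkeeping constants.
# The proton mass (not the hydrogen atom mass) is used for deprotonation so
# electron mass is accounted for; chloride adduction adds one electron.
.atomic_mass <- c(C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462,
                  P = 30.97376151, Cl = 34.96885271)
.proton_mass <- 1.00727646
.nh3_mass <- 17.02654910
.electron_mass <- 0.00054858

#' Elemental formula of a lipid species
#'
#' Standard construction rules for the negative-mode-relevant classes:
#' diacyl phosphatidic acid `PA(c:d) = C(c+3) H(2c+5-2d) O8 P`, diacyl
#' phosphatidyl-ethanolamine `PE(c:d) = C(c+5) H(2c+10-2d) N O8 P`, fatty
#' acid `FA(c:d) = C(c) H(2c-2d) O2`. The ether (O-) variant replaces one
#' ester by an ether bond (formula minus O plus 2 H); a plasmalogen
#' `P-(c:d)` shares the elemental formula of the ether species
#' `O-(c:d+1)` (the vinyl ether contributes one double-bond equivalent).
#' Only even total acyl carbon counts are accepted.
#'
#' @param class `"PA"`, `"PE"` or `"FA"`.
#' @param carbons Total acyl carbons (even).
#' @param double_bonds Number of double bonds.
#' @param linkage `"diacyl"` (or `"acyl"` for FA), `"ether"` (O-) or
#'   `"plasmalogen"` (P-); glycerophospholipids only.
#' @return Named integer vector of element counts (C, H, N, O, P).
#' @export
species_formula <- function(class = c("PA", "PE", "FA"), carbons,
                            double_bonds,
                            linkage = c("diacyl", "acyl", "ether", "plasmalogen")) {
  class <- match.arg(class)
  linkage <- match.arg(linkage)
  stopifnot(carbons > 0, carbons %% 2 == 0, double_bonds >= 0)
  if (class == "FA") {
    if (!linkage %in% c("diacyl", "acyl"))
      stop("ether/plasmalogen linkages are not defined for fatty acids")
    f <- c(C = carbons, H = 2 * carbons - 2 * double_bonds, N = 0, O = 2, P = 0)
  } else {
    d <- double_bonds
    if (linkage == "plasmalogen") { linkage <- "ether"; d <- d + 1 }
    f <- if (class == "PA")
      c(C = carbons + 3, H = 2 * carbons + 5 - 2 * d, N = 0, O = 8, P = 1)
    else
      c(C = carbons + 5, H = 2 * carbons + 10 - 2 * d, N = 1, O = 8, P = 1)
    if (linkage == "ether") { f["O"] <- f["O"] - 1; f["H"] <- f["H"] + 2 }
  }
  if (f["H"] <= 0) stop("invalid species: non-positive hydrogen count")
  storage.mode(f) <- "integer"
  f
}

#' Monoisotopic neutral mass of a formula
#'
#' @param formula Named integer vector of element counts as returned by
#'   [species_formula()] (elements among C, H, N, O, P, Cl).
#' @return Monoisotopic mass (Da).
#' @export
formula_mass <- function(formula) {
  stopifnot(!is.null(names(formula)),
            all(names(formula) %in% names(.atomic_mass)))
  sum(.atomic_mass[names(formula)] * formula)
}

#' Theoretical m/z of a negative-mode adduct ion
#'
#' `[M-H]-` removes a proton; `[M-NH3]-` removes neutral ammonia and a
#' proton (net loss of NH4, defined only for nitrogen-containing species —
#' the deammoniated anion characteristic of diathermy-aerosol ionisation of
#' ethanolamine lipids); `[M+Cl]-` adds a chloride (chlorine atom plus one
#' electron).
#'
#' @param formula Element count vector, see [species_formula()].
#' @param adduct One of `"[M-H]-"`, `"[M-NH3]-"`, `"[M+Cl]-"`.
#' @return Theoretical m/z (Da).
#' @export
adduct_mz <- function(formula, adduct = c("[M-H]-", "[M-NH3]-", "[M+Cl]-")) {
  adduct <- match.arg(adduct)
  m <- formula_mass(formula)
  switch(adduct,
    "[M-H]-" = m - .proton_mass,
    "[M-NH3]-" = {
      if (is.na(formula["N"]) || formula["N"] < 1)
        stop("[M-NH3]- requires a nitrogen-containing species")
      m - .nh3_mass - .proton_mass
    },
    "[M+Cl]-" = m + .atomic_mass[["Cl"]] + .electron_mass)
}

# "PA(34:1)", "PA(P-36:1)", "PE(O-34:2)", "FA(18:1)"
.species_name <- function(class, carbons, double_bonds, linkage) {
  pre <- switch(linkage, plasmalogen = "P-", ether = "O-", "")
  sprintf("%s(%s%d:%d)", class, pre, carbons, double_bonds)
}

.formula_string <- function(f) {
  paste0(vapply(names(f)[f > 0], function(el)
    if (f[[el]] == 1L) el else paste0(el, f[[el]]), character(1)),
    collapse = "")
}

#' Enumerate an in-silico negative-mode lipid ion database
#'
#' Builds all species over the configured class / carbon / double-bond /
#' linkage grid with their negative-mode adduct ions and theoretical m/z.
#' `[M-NH3]-` is generated only for nitrogen-containing classes (PE).
#' Defaults cover the glycerophospholipid and fatty-acid ions observed in
#' tissue REIMS spectra.
#'
#' @param classes Headgroup classes to enumerate.
#' @param gpl_carbons Even total acyl carbons for glycerophospholipids.
#' @param fa_carbons Even carbons for fatty acids.
#' @param double_bonds Double-bond counts.
#' @param linkages Linkage variants for glycerophospholipids.
#' @param adducts Adduct set.
#' @return data.frame: `species`, `class`, `carbons`, `double_bonds`,
#'   `linkage`, `formula`, `adduct`, `mz`.
#' @export
lipid_database <- function(classes = c("PA", "PE", "FA"),
                           gpl_carbons = seq(24, 44, by = 2),
                           fa_carbons = seq(12, 26, by = 2),
                           double_bonds = 0:6,
                           linkages = c("diacyl", "ether", "plasmalogen"),
                           adducts = c("[M-H]-", "[M-NH3]-", "[M+Cl]-")) {
  rows <- list()
  for (cl in classes) {
    carb <- if (cl == "FA") fa_carbons else gpl_carbons
    lks <- if (cl == "FA") "acyl" else linkages
    for (ca in carb) for (d in double_bonds) for (lk in lks) {
      f <- tryCatch(species_formula(cl, ca, d, lk), error = function(e) NULL)
      if (is.null(f)) next
      for (ad in adducts) {
        if (ad == "[M-NH3]-" && f[["N"]] < 1) next
        rows[[length(rows) + 1L]] <- data.frame(
          species = .species_name(cl, ca, d, lk), class = cl, carbons = ca,
          double_bonds = d, linkage = lk, formula = .formula_string(f),
          adduct = ad, mz = adduct_mz(f, ad), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Match an observed m/z against the lipid ion database
#'
#' Returns every candidate ion whose theoretical m/z lies within the
#' tolerance of the query, sorted by absolute mass error. An empty result
#' is a valid outcome.
#'
#' @param query_mz Observed m/z (Da).
#' @param tolerance Match tolerance (Da), default 0.1.
#' @param database Ion table from [lipid_database()].
#' @return The matching database rows plus `query_mz` and `error`
#'   (theoretical minus query, Da), sorted by `abs(error)`.
#' @export
annotate_mz <- function(query_mz, tolerance = 0.1, database = lipid_database()) {
  stopifnot(is.numeric(query_mz), length(query_mz) == 1, tolerance > 0)
  hits <- database[abs(database$mz - query_mz) <= tolerance, , drop = FALSE]
  hits$query_mz <- rep(query_mz, nrow(hits))
  hits$error <- hits$mz - query_mz
  hits <- hits[order(abs(hits$error)), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
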