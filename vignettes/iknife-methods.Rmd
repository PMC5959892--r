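---
title: "Methods: spectral tissue recognition with reims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral tissue recognition with reims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reims)
```

This vignette documents the statistical model, the preprocessing
conventions, the synthetic-cohort generator and the numerical and design
choices made where the methodology was genuinely open. It is the package's
reference for *why* the pipeline is built the way it is; the README shows
*how* to run it.

## The recognition model

Each burn produces a centroided negative-ion peak list. After
preprocessing (below), a spectrum is a 4000-vector of total-ion-current
(TIC) normalised intensities over 0.1 Da bins spanning 600–1000 *m/z*, the
lipid-dominated region of diathermy aerosol spectra.

Classification is PC-LDA, the standard model for whole-spectrum tissue
fingerprinting:

* **PCA stage.** Spectra are mean-centred and projected onto the top
  $k$ principal components (`n_pcs`, default 25). PCA here is purely a
  variance-capturing compression; no per-peak feature selection is done —
  the model is deliberately a whole-spectrum fingerprint.
* **LDA stage.** In PC space each class $c$ is modelled as Gaussian with
  mean $\mu_c$ and a *pooled* within-class covariance $\Sigma$. Posteriors
  follow Bayes' rule,
  $P(c \mid z) \propto \pi_c \exp\!\big(-\tfrac12 (z-\mu_c)^\top
  \Sigma^{-1} (z-\mu_c)\big)$.
* **Thresholded recognition.** The call is the posterior argmax; its
  posterior is the *reliability*. Calls with reliability below the
  threshold (default 0.75) are withheld rather than reported, mirroring
  how real-time recognition software suppresses unreliable
  classifications. Reliability-as-maximum-posterior is an interpretation:
  the proprietary recognition software does not publish its score, only
  its thresholding behaviour, which is what we reproduce.

Assumptions worth stating: equal class covariances (pooled $\Sigma$),
approximate Gaussianity in PC space, and priors that do **not** follow
training-class sizes. Priors default to equal (`priors = "equal"`)
because class counts in surgical cohorts reflect tissue availability, not
prevalence; `"proportional"` is available.

### Numerical choices

* **Ridge.** With 25 PCs and a few dozen spectra per class the pooled
  covariance can be near-singular, so $\lambda \cdot
  \overline{\mathrm{diag}(\Sigma)}$ is added to the diagonal
  ($\lambda$ = `ridge`, default $10^{-6}$). If the within-class variance
  is exactly zero (degenerate noiseless input) an absolute floor of
  $10^{-10}$ keeps the fit invertible; posteriors then collapse onto the
  nearest class, which is the sensible limit.
* **Sign convention.** Each PC loading is flipped so its first
  non-negligible element is positive, making score plots reproducible.
* **Rank handling.** `n_pcs` above the matrix rank is reduced with a
  warning rather than an error, since cross-validation folds shrink the
  training set.
* **Posterior stability.** Log-densities are shifted by their row maximum
  before exponentiation, so posteriors are invariant to any constant
  offset and never overflow.

## Preprocessing conventions

* **Lock-mass correction** (`lock_mass_correct()`): the most intense peak
  within ±0.3 Da of the reference (internal lock mass 699.497 *m/z* for
  frozen-tissue work; leucine enkephalin 554.2615 *m/z* externally for
  fresh tissue) defines a constant shift subtracted from every *m/z*. A
  single-point additive correction is sufficient because drift on
  time-of-flight instruments in this setting is well below 0.1 Da; a
  ppm-proportional model would add a parameter without measurable benefit.
  A missing lock peak yields a warning and an uncorrected spectrum — not
  an error, since blind spectra must still flow through.
* **Background subtraction** (`subtract_background()`): the 5th-percentile
  peak intensity is taken as a flat per-spectrum baseline, subtracted and
  clipped at zero. The original acquisition chain delegates this step to
  proprietary software with an unpublished algorithm; a low-quantile rule
  was chosen as the simplest auditable surrogate.
* **Binning** (`bin_spectrum()`): bins are left-closed right-open
  intervals labelled by their lower edge, so no peak can be double
  counted, and binning conserves in-window intensity exactly. Edge
  membership uses a $10^{-6}$-bin-width snap so printed edge values
  (e.g. 700.1) land in the bin they label despite floating-point
  representation.
* **Normalisation** (`normalize_tic()`): rows are divided by their total.
  Whether the original software normalised to TIC, median or a reference
  peak is not published; TIC was chosen and recorded in the matrix's
  `normalization` tag so alternatives can be compared. Spectra with raw
  in-window signal below 10 counts are QC-rejected and logged (modelling
  the "no interpretable signal" exclusion).

A consequence of TIC normalisation worth knowing: it is compositional.
When cancer elevates a few large peaks, every *other* normalised bin
shrinks in cancer, so non-discriminant bins acquire modest negative
fold changes. This is visible in the shortlist output and is a property
of the scale, not a bug; the generator's ground truth is therefore
validated on *raw* binned intensities in the tests.

## Cross-validation and metrics

Leave-one-patient-out CV holds out **all** spectra of one patient per
fold, because burns of one patient are correlated (shared biology,
acquisition session); spectrum-level CV would leak that correlation and
flatter the model. Sample-level calls aggregate a sample's burns by
majority vote, with ties broken by mean posterior — the simplest auditable
rule, since the original work reports sample-level tables without stating
its aggregation. Both spectrum- and sample-level confusions are reported.
Folds whose held-out class is absent from training are logged as
degenerate and excluded from per-class metrics instead of polluting them.

Sensitivity is per-class recall; specificity is one-vs-rest. Reported
percentages use half-up rounding at one decimal (so 38/39 prints as 97.4),
matching how such tables are conventionally printed; raw fractions are
retained alongside.

## Univariate discovery

Bins are tested with rank tests (Wilcoxon rank-sum for two classes,
Kruskal–Wallis above that; tie-corrected normal/χ² approximations). Test
units default to **per-sample mean spectra**: burns within a sample are
pseudo-replicates, and testing them as independent units would inflate
significance. The spectrum level is available for sensitivity analysis.

FDR control uses the Benjamini–Yekutieli step-up, which is valid under
arbitrary dependence — adjacent spectral bins are strongly dependent, so
the plain Benjamini–Hochberg assumption is not defensible as a default
(it remains available behind `method = "BH"`). Constant bins get $P = 1$
by convention and are flagged. Fold changes are medians with a
pseudo-count of one tenth of the smallest positive intensity, keeping
zero-median bins finite and antisymmetric. The reporting shortlist
filters to $P < 0.001,\ q < 0.001$ and ranks by pooled median intensity —
"most significant and intense" — defaulting to ten bins.

## Inter-rater agreement

Unweighted Cohen's κ (tissue classes are nominal) with the marginal-based
null-hypothesis standard error (Cohen 1960 / Fleiss) for $z$ and a
two-sided normal $P$; software implementations vary here and the original
analysis does not name its formula, so the inputs are always reported
alongside. Verbal bands follow the conventional scale; the published
banding leaves (0.80, 0.81) undefined, and we close it upward ("very
good" covers everything above 0.80) so the printed ≥ 0.81 examples keep
their labels and no gap remains.

## Lipid annotation

The in-silico database enumerates PA, PE (diacyl, ether O-, plasmalogen
P-) and fatty acids over even total acyl carbons (24–44 for
glycerophospholipids, 12–26 for FA) and 0–6 double bonds, with
[M−H]⁻, [M−NH₃]⁻ (nitrogen-bearing species only) and [M+Cl]⁻ ions.
Monoisotopic masses use proton-mass bookkeeping so electron mass is
carried correctly; [M−NH₃]⁻ is interpreted as loss of neutral ammonia
*plus* deprotonation (net −NH₄), which is the reading that reproduces the
well-known PE(34:1)/PA(36:2) isobar at 699.497. A plasmalogen P-(c:d)
shares the formula of the ether species O-(c:d+1). Computed masses are
reported as computed — e.g. PA(P-36:1) [M−H]⁻ gives 685.5178 where 685.517
is sometimes printed — rather than snapped to published values. Matching
uses ±0.1 *m/z* by default. Phosphatidylcholines and sphingolipids are
out of scope (not assigned in this tissue context), as is MS/MS fragment
interpretation.

## The synthetic cohort generator

Because surgical REIMS cohorts are not publicly deposited, the package
ships a generator whose defaults define its reference study: 3 tissue
classes (normal, borderline, cancer) × 10 patients × 2 samples × 3 burns;
20 lipid peak templates of which 5 are discriminant, planted at 673.481,
685.517, 699.497, 742.539 and 744.555 *m/z* with maximum fold change 4;
patient effect SD 0.2 and burn noise SD 0.1 (log-intensity scale);
background amplitude 1% of the median template intensity (50 peaks per
spectrum at uniform random *m/z*); calibration drift SD 0.02 Da; lock mass
699.497.

The intensity model is multiplicative log-normal — the standard behaviour
of MS intensities:
$I_{t,b} = \text{base}_t \cdot \text{fold}_{t,c} \cdot e^{u_p} \cdot
e^{\varepsilon_{t,b}}$ with one shared patient offset
$u_p \sim N(0, \sigma_\text{patient})$ (creating the within-patient
correlation that makes LOPOCV strictly harder than spectrum-level CV) and
i.i.d. per-peak burn noise $\varepsilon_{t,b} \sim
N(0, \sigma_\text{burn})$. The burn noise is drawn per peak rather than
once per burn: a single shared per-burn factor would be removed exactly by
TIC normalisation and the parameter would be dead. Calibration drift is a
per-spectrum constant shift applied to *every* peak including the lock
mass, so lock-mass correction can undo it exactly — a deliberate closure
property used by the tests.

Fold-change directions had to be chosen, since a three-class design is
not fully pinned down by published two-class contrasts: cancer is elevated
four-fold at 673.481/685.517, 699.497 and 742.539 carry a 2/4 gradient
(normal/borderline/cancer) so borderline sits intermediate, and 744.555
is elevated in borderline. This keeps all three classes mutually
separable while preserving the qualitative facts that 699 and 744 are
among the most abundant peaks everywhere and 699 is higher in cancer.
Cancer samples are generated at 100% tumour content so the
tumour-content filter (cutoff 50%, strict) is inert on synthetic data
unless exercised deliberately.

What the generator does **not** emulate: chromatographic/time structure,
isotope envelopes, detector saturation, peak-shape effects, heteroscedastic
mass error, or histology-driven within-sample heterogeneity (each sample
is homogeneous tissue). Passing tests on synthetic cohorts therefore
demonstrate the *statistical machinery* — leakage-free validation,
calibrated FDR, exact preprocessing closure — not clinical performance on
real tissue, which only a real annotated cohort can show.

## Problem sizes

The reference scenario (180 spectra, 4000 bins, 30 LOPOCV folds) was
chosen so a full simulate–preprocess–crossvalidate–discover cycle runs in
seconds on a single core, which keeps the whole suite and the acceptance
script cheap enough to run routinely; the test suite uses smaller cohorts
(4–6 patients, 1–2 samples) for property checks and 20-replicate
calibration loops. Statistical conclusions (FDR control, threshold
monotonicity) are asserted with slack appropriate to those sizes.

## Known limitations

* The PC-LDA posterior is only an interpretation of the proprietary
  "reliability" score; absolute reported-fraction numbers depend on it.
* One global lock-mass shift per spectrum; no nonlinear mass-axis warping.
* TIC normalisation is compositional (see above); fold changes on the
  normalised scale mix signal and closure effects.
* Kappa uses the asymptotic null SE; exact small-sample inference is not
  implemented.
* The annotation database scores by mass error alone — no isotope-pattern
  or MS/MS evidence — so isobars (e.g. at 699.497) are returned as ties,
  as they should be.
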