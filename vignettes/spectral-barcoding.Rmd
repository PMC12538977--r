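---
title: "Spectral barcoding of CSF Raman spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral barcoding of CSF Raman spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical method it
implements: what is computed at each stage, which parameters matter and
why their defaults are what they are, what the synthetic cohort generator
does and does not emulate, and which design decisions were genuinely open.

## The problem

CSF Raman spectroscopy measures a vibrational fingerprint of the
cerebrospinal-fluid proteome: per patient, ~30 replicate spectra of a
dried droplet, 1015 channels covering 659–1761 cm⁻¹ (≈1.09 cm⁻¹ per
channel). The analytical question is whether Alzheimer's disease leaves a
reproducible signature in this fingerprint, whether that signature can be
reduced to a small set of interpretable band-area features (a "spectral
barcode"), and whether those features track the established CSF ATN
biomarkers (Aβ42, p-tau 181, total tau).

## Preprocessing model

Raw spectra are modelled as

> signal + fluorescence baseline + patient offset + channel noise +
> occasional cosmic-ray spikes,

and each term is removed by a dedicated stage, in the order applied by
`preprocess_pipeline()`:

* **Background subtraction** (optional): the pointwise mean of three
  substrate spectra is subtracted.
* **Spike removal** (`remove_spikes`): channels whose modified z-score
  against a 7-channel rolling median exceeds 8 are replaced by that
  median. The window/threshold pair was chosen so the filter can never
  trigger on a Lorentzian band of the default 6 cm⁻¹ width: a genuine band
  spans many channels and never deviates from its local median by eight
  robust SDs. When a spectrum is so smooth that the median absolute
  residual is zero, the scale falls back to the first-difference MAD so
  spikes on noiseless spectra are still caught.
* **Haar-wavelet denoising** (`denoise_wavelet`): 6 decomposition levels;
  detail coefficients are soft-thresholded at the universal threshold
  σ√(2 ln n) with σ estimated per spectrum from the finest-level median
  absolute deviation (MAD/0.6745). This rule is parameter-free, which is
  why it was chosen over tunable alternatives. 1015 channels are not
  dyadic, so spectra are padded symmetrically to 1024 before
  decomposition and truncated after reconstruction.
* **Baseline subtraction** (`subtract_poly_baseline`): a fifth-order
  polynomial least-squares fit over the axis is subtracted — the standard
  order for broadband biofluid fluorescence.
* **Rubberband anchoring** (`rubberband_anchor`): the chord through the
  first and last intensity values is subtracted so both end channels sit
  exactly at zero. Since the polynomial step has already removed the
  curved baseline, end-point anchoring (rather than a full convex-hull
  rubberband) suffices; the convex-hull variant remains available via
  `convex_hull = TRUE`.
* **Vector normalisation** (`vector_normalize`): each spectrum is scaled
  to unit Euclidean norm, removing overall intensity variation (droplet
  thickness, focus).

### Outlier screening

Screening runs on the preprocessed spectra at two levels: within each
patient across replicates (`pca_outliers_spectra`), and across patients on
the patient-mean spectra (`pca_outliers_patients`). Both use the same
score: PCA on the relevant matrix, robust z-scores
((score − median)/MAD) of the first 3 PC scores, combined as the
root-mean-square over components, compared to a 3-SD threshold.

The combination rule was a real design choice. Flagging on *any* PC
exceeding 3 robust SDs would tag ≈0.3 % of clean items per component by
construction — with 143 patients and 3 PCs, roughly one clean patient per
cohort. The RMS combination requires either a genuinely extreme excursion
on one component or coordinated deviations on several, which drops the
clean false-flag rate to effectively zero while a contaminated sample
(whose broadband distortion projects almost entirely on one component,
tens of robust SDs out) still exceeds the threshold comfortably.
Components with zero spread are excluded from the average so that
degenerate designs (e.g. 29 identical replicates plus one deviant) are
still screened.

Every stage appends an entry to the set's provenance log;
`replay_steps()` re-applies the log to the raw input and reproduces the
processed set bit-exactly, including the outlier removals.

## The spectral barcode

`mannwhitney_per_shift()` runs a two-sided Mann–Whitney U test at every
channel between the AD and non-AD training spectra. Exact p-values (from
the null U distribution) are used when both groups have fewer than 20
spectra and the channel is tie-free; otherwise the normal approximation
with tie and continuity correction. `extract_regions()` turns the p-value
track into regions: maximal runs of channels with p < α (default 0.01),
runs separated by at most `max_gap = 2` non-significant channels merged,
runs narrower than `min_width = 3` channels discarded. The gap and width
defaults encode the physical prior that real Raman bands are several
cm⁻¹ wide — an isolated single-channel hit at α = 0.01 among 1015
channels is noise. Each region carries one sign (the majority channel
direction of the AD-minus-non-AD mean difference), its smallest channel
p-value, and a significance rank (ties broken toward the lower
wavenumber).

Each region is then reduced to its **area**: the trapezoidal integral of
the preprocessed (vector-normalised) intensity over the region's
channels, with no local baseline re-subtraction — normalisation is the
last preprocessing step, so areas are computed on the final
representation. `rank_features()` re-ranks regions by a Mann–Whitney test
on the areas themselves, which is the ranking the feature names
(feature 1 = most significant) refer to.

Whether area should be measured above zero or above a local chord was
ambiguous; above zero was chosen because the rubberband step has already
anchored the spectrum and any local chord would re-introduce a
region-specific baseline model.

## Classification and evaluation

`stratified_split()` samples, per class, the nearest integer to 80 % of
that class's patients into training (66 AD + 75 non-AD → 113 train / 28
test). All replicate spectra of a patient follow the patient.

Two model families are provided behind one interface: **bagged decision
trees** (random forest with `mtry` = number of features, i.e. pure
bootstrap aggregation) on the barcode areas, and a **linear SVM** on the
PCs retaining 95 % of the training-spectrum variance
(`pca_reduce_fingerprint`; the projector is fitted on training spectra
only and reused verbatim on test spectra). Hyperparameters are tuned by a
seeded 20-candidate random search (tree count/size/leaf size; SVM cost on
a log scale), each candidate scored by 5-fold cross-validated AUC with
**folds grouped by patient** — replicate spectra of one patient are never
split across folds, otherwise replicate correlation leaks into the CV
estimate. `model_spec(grouped_cv = FALSE)` reproduces the laxer ungrouped
reading. Misclassification costs default to equal, with a
`class_weights` override.

The tuned model is refitted 10 times with reshuffled CV groups
(`retrain_ensemble`); variability is summarised as the SEM of the CV AUC,
and test-set scores are averaged across the retrains. Per-spectrum hard
calls (majority over retrains) are aggregated into the per-patient
**classification score** = 100 × (# spectra called AD)/(# spectra).
`roc_with_mop()` computes the empirical ROC over all distinct thresholds,
AUC by the trapezoid rule, and the model operating point as the threshold
maximising Youden's J (ties toward higher specificity). `metrics_table()`
reports accuracy, sensitivity, specificity, PPV, NPV, F1 and AUROC at the
operating point, with zero-denominator cells returned as explicit
undefined values rather than NaN.

A convolutional-network model is deliberately out of scope (no published
architecture to implement); the `model_spec()` interface is the seam
where one would plug it in.

## Feature importance

`global_surrogate_importance()` perturbs the z-scored features around
each queried training point (Gaussian perturbations, default 1000 per
point), weights perturbations by a Gaussian kernel of width **0.5 in
standardised feature space** (the usual convention for that constant),
fits a depth-limited regression tree to the black-box scores, and uses
the surrogate's normalised variable importance as the local weights;
global importance is the mean absolute local weight. The tree surrogate
(rather than a linear one) matches the tree-based black box. The number
of queried points is capped (`max_points`) for runtime; importances are
means, so subsampling only adds Monte-Carlo noise.
`partial_dependence()` computes PD(v) = mean prediction with feature j
forced to v over a uniform grid spanning the observed range, and reports
the curve and its maximum.

## Biomarker scoring and partial correlations

`plm_score()` counts positive ATN biomarkers per patient — A: Aβ42 <
680 pg/ml, T: p-tau > 56 pg/ml, N: total tau > 355 pg/ml (strict
inequalities; a value exactly at a cutoff is negative) — yielding the
ordinal 0–3 PLM scale; patients missing any component get an undefined
score. PLM status enters correlations as the 0–3 numeric.

`partial_correlation()` residualises both variables on age and a 0/1 sex
indicator by least squares and reports the Pearson correlation of the
residuals, with p from t = r√((n−2−k)/(1−r²)) on n−2−k degrees of
freedom. Biomarker concentrations are natural-log-transformed; the log
base is immaterial for correlations (a linear rescaling of the log), as
is the 0/1 direction of the sex code — both invariances are asserted in
the tests. Feature–biomarker tests form **one BH family of 30** (10
features × 3 biomarkers, `correlation_matrix()`); classifier-score/
feature–PLM tests form a **separate family** (`plm_correlations()`).
Patients missing total tau are excluded from the total-tau column only.

## The synthetic cohort generator

`simulate_cohort()` draws cohorts with the statistical structure the
analysis assumes:

* **Template**: a sum of Lorentzian bands (default FWHM 5–30 cm⁻¹) at
  standard protein positions; peak profiles are Lorentzian because that
  is the canonical Raman line shape.
* **Class effects**: ten regions (the eight reported feature intervals
  996–1001, 1003–1010, 740–771, 1328–1338, 1480–1496, 1189–1203,
  1366–1374, 1747–1751 cm⁻¹, plus two configurable placeholders at
  1076–1086 and 1650–1660 cm⁻¹ standing in for the two intervals whose
  bounds are not recoverable) with alternating signs. Effects are
  **multiplicative** scalings of the template inside the region — a
  concentration change scales a band, it does not add an offset — and
  their magnitude is expressed in units of the baseline within-class SD
  of the region's raw area (closed form from the channel-noise and
  patient-offset variances), so "a 1-SD effect" means the class means
  differ by one within-class SD of that feature. The default magnitude is
  1 SD: large enough to be detectable in a ~70-patients-per-class cohort,
  small enough that single spectra are far from separable — the regime a
  real biomarker study lives in.
* **Patient structure**: a latent severity s (AD ~ N(1, 0.3), non-AD ~
  N(0, 0.3)) multiplies the injected effects, making them
  patient-consistent (which is what patient-level aggregation exploits),
  plus an additive per-patient intensity offset (SD 0.01).
* **Nuisance terms**: an order-5 polynomial baseline with per-spectrum
  random coefficients, additive Gaussian channel noise (SD 0.02 against
  peak amplitudes ≤ 1), and Poisson cosmic-ray spikes (rate 0.05 per
  spectrum, amplitude ~20).
* **Biomarkers**: class-conditional log-normals (AD centred at 420/80/500
  pg/ml for Aβ42/p-tau/total tau, non-AD at 950/35/240, log-SDs
  0.30–0.40, straddling the PLM cutoffs as a diagnostic cohort does),
  correlated with the latent severity at ρ = ±0.5 (negative for Aβ42).
  Total tau is missing for a configurable fraction (default 7/143).
  Ages and sex frequencies differ by class (AD 64 ± 9 y, 43 % male;
  non-AD 68 ± 11 y, 71 % male).
* **Contamination**: `inject_contamination()` adds a broad Gaussian band
  (centre 1250 cm⁻¹, SD 200 cm⁻¹ — far wider than any fingerprint band)
  to all spectra of selected patients, emulating blood contamination.

What the generator does **not** emulate: drying-pattern (coffee-ring)
spatial heterogeneity, wavenumber calibration drift, detector etaloning,
correlated (pink) noise, or real biochemical covariance between bands.
Passing tests therefore demonstrate that the pipeline recovers the
structure this model encodes — localised class effects, patient-consistent
severity, biomarker coupling — not that it would achieve any particular
performance on real instrument data.

Identical configurations (including the seed) reproduce cohorts
bit-exactly; every stochastic stage of the pipeline takes an explicit
seed.

## Numerical choices and degenerate inputs

* Mann–Whitney switches from exact to normal-approximate p-values at
  group size 20, with continuity correction, matching the behaviour of
  the standard two-sample implementation it is tested against.
* Channels whose pooled values are all tied get p = 1 (zero-variance
  guard), and a channel with identical class distributions is never
  significant.
* PCA outlier components with zero spread are dropped from the score;
  patients with fewer than n_pcs + 2 replicates are skipped with a
  warning rather than screened.
* The Fisher discriminant adds a small ridge to a singular within-class
  covariance and says so; `linear_cutoff_accuracy` breaks threshold ties
  toward the lower cutoff.
* Region areas use the trapezoid rule, so a single-channel region has
  area zero by convention.
* Metrics with empty confusion-matrix margins (PPV/NPV under one-sided
  predictions, AUROC with one class) are reported as undefined and
  flagged, never as NaN arithmetic.

## Simulation sizes used by the test suite

The stochastic suites run at sizes chosen to give stable Monte-Carlo
averages: barcode recovery uses 50 cohorts of 40 patients per class with
10 replicate spectra (recovery is a property of patient count and effect
size, not replicate count, so 10 replicates suffice); the null
calibration uses 40 such cohorts; the power curve uses 50 cohorts per
effect size {0, 0.5, 1, 2} SD at 20 patients per class; FDR control uses
500 null families of 30 tests at the full 141-patient size. The
contamination fixture runs at the full 143 patients × 30 spectra.

## Known limitations

* The barcode's region-merging rule (gap 2, width 3) is a heuristic; the
  aggregation that produced the originally reported region widths is not
  recoverable from published information, so recovered regions can split
  or fuse relative to any particular reference barcode.
* Surrogate importance depends on the perturbation distribution; only
  rank stability, not the absolute importance values, should be
  interpreted.
* With strongly imbalanced classes the balanced-accuracy cutoff of
  `linear_cutoff_accuracy` can trade overall accuracy for balance; both
  numbers are reported.
* The generator's independence assumptions (white noise, independent
  baselines) make preprocessing somewhat easier than on real spectra;
  real-data performance claims are outside what this package can
  establish.
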