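---
title: "Estimating intra-puparial age from organ staging and puparium FTIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intra-puparial age from organ staging and puparium FTIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pupage` estimates the age of a *Chrysomya nigripes* pupa — hours since
pupariation — from two independent lines of evidence, and intersects them
into a single PMI_min window. This vignette explains the model behind each
track, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
that were genuinely open.

## The morphological track

### Data model

During the intra-puparial period seven organ systems (compound eyes,
abdomen, thorax, mouthparts, antennae, wings, legs) pass through 6–8
discrete, visually scorable sub-stages. The packaged tables record, for
each (organ, sub-stage, temperature) combination at 19, 22, 25, 28, 31 and
34 °C, the earliest (`h_min`) and latest (`h_max`) hours after pupariation
at which the sub-stage was observed, with standard deviations across
replicate cohorts. Four organs also have a timed "organ not yet visible"
state; we model it as a usable pseudo-sub-stage `ABSENT`, because "the
antennae are not yet visible" is a legitimate, informative field
observation with its own printed window. Cells printed as "-" (a sub-stage
never recorded at that temperature, e.g. legs II at 34 °C) load as missing
with an `absent` flag, never as zero.

Two conventions matter for interpretation:

* The source observations were made every 8 h, so `h_min`/`h_max` are
  first/last *observation* times, not true onset/offset times. We treat
  them as conservative bounds; the gap-coverage test in the suite verifies
  that consecutive windows never leave a hole larger than one sampling
  interval plus the printed SDs.
* The tables contain printed anomalies — the antennae series at 28 °C has
  `h_min` falling from 48 (II) to 44 (III), and there are a few more
  non-monotone steps in the antennae columns. These are preserved verbatim
  and surfaced by `validate_staging_tables()`; silently "correcting"
  published data is out of bounds. A checksum test pins the fixture to the
  transcription.

### Estimation

An observation (organ *o*, sub-stage *s*) at temperature *T* constrains age
to `[h_min, h_max]` of that record. `estimate_age()` intersects the windows
of all observations; adding evidence can only narrow the window, and the
result carries a provenance log naming every contributing record.

* **Off-grid temperatures** (19–34 °C) interpolate `h_min` and `h_max`
  linearly between the flanking grid temperatures. No thermal-summation
  (accumulated-degree-hour) model is fitted — the tables provide six grid
  points and nothing licenses a stronger functional form; linearity between
  neighbours is the minimal assumption and is labelled in the provenance.
  Below 19 °C development fails entirely, so extrapolation raises an error
  rather than guessing.
* **Conflicting observations** (disjoint windows) raise an error naming
  the incompatible pair. This is deliberate: an impossible combination
  means a staging error or mixed evidence, which the analyst must resolve.
  `union = TRUE` returns the convex hull with a warning for triage.
* **SD widening** (`widen_by_sd = TRUE`) extends each bound by its printed
  SD. Off by default: the bare min/max are the primary published windows
  and the SDs describe between-cohort scatter, not a confidence interval.

`total_duration(T)` — pupariation to eclosion — is the maximum over organs
of the terminal sub-stage's `h_max`: 192 h at 19 °C falling to 77.3 h at
34 °C on the packaged tables.

## The spectral track

### Preprocessing

ATR-FTIR spectra of the puparium cuticle are processed in a fixed order:

1. **Crop** to the 1800–900 cm⁻¹ fingerprint region (closed interval; 226
   points on a 4 cm⁻¹ grid).
2. **Savitzky–Golay smoothing**, 5-point window. The polynomial order is
   not dictated by the protocol; order 2 is the standard choice compatible
   with a 5-point window and is configurable. The interior kernel is the
   least-squares solution `(-3, 12, 17, 12, -3)/35`; edges are mirror-padded,
   which keeps the output length and confines any bias to the outer two
   points.
3. **Standard normal variate**: each spectrum is centred and scaled to unit
   *sample* (n−1) standard deviation — stated explicitly so tests are
   unambiguous. SNV removes per-contact gain and offset, making the whole
   chain invariant to affine transformations of the raw absorbances
   (property-tested).
4. **Baseline correction.** The default subtracts the straight line through
   the first and last grid points — exactly reproducible and sufficient
   after SNV on this narrow window. An asymmetric-least-squares baseline
   (`lambda`, `p` configurable; defaults 1e5 and 0.01) is available for
   curved backgrounds.
5. **Mean centering** across samples (per wavenumber), the state PCA
   expects.

Replicate averaging (five spectra per time point collapsed to one) is part
of the acquisition protocol and is the default (`average = "before"`), but
classification needs within-class replication, so the evaluation pipeline
runs with `average = "none"`. Both paths are supported because the
acquisition description and the split protocol pull in opposite
directions; which one a study used changes the effective sample size
entering the split.

### Classification protocol

The preprocessed matrix is reduced by PCA (SVD of the centred matrix;
explained variance = squared singular values, signs fixed so each
component's largest-magnitude loading is positive). The components feeding
the classifiers default to the smallest number explaining ≥ 95 % of
variance, capped at 15 — configurable, and worth attention: on data whose
age signal is nearly one-dimensional the discriminative curvature can hide
in low-variance components, so a fixed `n_components` of 5–10 can
outperform the variance rule.

Each of `n_repeats = 3` seeded repetitions draws a stratified 60/40
train/validation split (per class, `round(0.6·n)` to training, at least one
sample on each side) and runs two classifiers on the training scores:

* **PLS-DA**, written from scratch as NIPALS PLS2 on the one-hot class
  indicator matrix, 5 latent variables by default (capped at
  `min(n_train − 1, p)`). Two decision rules are provided. `"max"` assigns
  the class with the largest predicted indicator response, ties to the
  lowest class index. `"centroid"` (the evaluation default) assigns the
  nearest training-class centroid in latent score space. The max rule is
  the textbook reading of discriminant PLS, but with more than two *ordered*
  classes it inherits the masking defect of least-squares indicator
  regression: interior classes' fitted responses are never maximal, and on
  day-course spectra the micro accuracy saturates well below what the data
  support (we measured ≈ 0.83 on noiseless synthetic day classes, errors
  all adjacent interior days, at any effect size). The centroid rule is
  standard in chemometrics software, agrees with the reference
  implementation (tested against mixOmics for both rules), and resolves
  the masking without touching the fitted model.
* **Random forest** (500 trees, `floor(sqrt(p))` features per split),
  delegated to the `randomForest` package and seeded per repetition.

Validation predictions give a confusion matrix (rows = true, columns =
predicted) and metrics under one-vs-rest reduction: per class, accuracy
`(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
`F1 = 2PR/(P+R)`; macro metrics are unweighted means over classes. The
binary formulas plus macro means only cohere under one-vs-rest reduction,
which is why that reduction is used. When a denominator is zero the metric
is defined as 0 and the event is logged in the report. Because
macro-accuracy is inflated by true negatives in multi-class problems, the
overall (micro) accuracy `trace/total` is always reported alongside and
labelled distinctly. Repetition metrics are averaged arithmetically.

### From class to hours, and fusion

Spectral sampling is daily, so a predicted class of day *d* at temperature
*T* maps to `[24d, min(24(d+1), total_duration(T))]` — clipping keeps the
window inside the biologically possible range. An empty puparium maps to
`[total_duration(T), ∞)`: spectra cannot say how long ago the adult left.
One known tension: at 19 °C eclosion is observed up to 216 h in spectral
sampling, while the staging tables end at 192 h; the package uses the
table value and documents the discrepancy here. Fusion intersects the
morphological and spectral windows; disjoint windows set a conflict flag
and both sources are reported unfused, because in casework each line of
evidence must stay visible.

## The synthetic-spectra generator

No public spectra exist for this system, so the generator provides
datasets with the right *structure* for exercising the pipeline:

* Gaussian bands at 1632 (amide I), 1516 (amide II), 1395 (COO⁻ of free
  fatty acids/amino acids — decays with age), 1240 (amide III/C–O), 1080
  and 1030 cm⁻¹ (phosphate/carbohydrate), with amplitudes
  `base·(1 + effect·slope·fraction)` linear in the development fraction;
* a distinct empty-puparium amplitude profile (protein bands attenuated,
  cuticular carbohydrate bands enhanced), also scaled by `effect_size` so
  that `effect_size = 0` collapses *every* class to one mean profile;
* per-spectrum linear baseline drift (uniform slope, half-range 1e-4
  absorbance/cm⁻¹) and i.i.d. Gaussian noise (SD 0.01 absorbance units);
* the acquisition design: 5 replicates per 24-h time point per temperature
  (19/25/31 °C), day classes running until eclosion by the packaged
  `total_duration`, plus the terminal empty-puparium class.

Band slope magnitudes, noise SD and drift range are conventions — nothing
in the underlying study quantifies them — chosen once to give realistic
within-class scatter and adjacent-class overlap at `effect_size = 1`. What
the generator does **not** emulate: Lorentzian/Voigt line shapes,
atmospheric CO₂/H₂O features, ATR penetration-depth dispersion, detector
nonlinearity, and — most importantly — multi-dimensional age chemistry.
Because band amplitudes are affine in the development fraction, all class
means lie on a 1-D manifold (curved only by SNV); real puparium chemistry
is richer. Passing tests therefore demonstrate that the pipeline recovers
structure that is present and reports chance when it is absent; they do
not certify classification accuracy on real cuticle spectra.

## Numerical choices

* Interval arithmetic is closed-interval throughout; degenerate windows
  (`h_min = h_max`, e.g. wings I at 34 °C) are valid.
* PCA uses LAPACK SVD; rank is the count of singular values above
  `max(d)·1e-10`; requesting more components errors.
* NIPALS iterations stop when the score vector changes by less than
  `1e-12` relative norm (500-iteration cap); with one response column the
  loop converges in one pass.
* Mean-centred columns are checked to `1e-10`; SNV and kernel identities to
  `1e-12`; PCA-vs-eigendecomposition to `1e-8`.
* Spectra CSVs are written with `%.17g` and parsed with base `strtod`, so a
  write/read round trip is bit-exact.
* All stochastic steps (splits, forests, generator) run under explicit
  seeds via `withr::with_seed`; repetition *r* uses `seed + r − 1`.

## Problem sizes used by the test suite

The suite and the acceptance script run at the design's own scale: 20–30
spectra per dataset (4–8 day classes × 5 replicates, 226 wavenumbers),
three repetitions per evaluation, 50 seeded splits for the chance-level
check (10 generated datasets × 5 splits) and three datasets at
`effect_size = 3` — the documented "strong effect" — for the recovery
check. Forest sizes are reduced to 50–200 trees in tests; the package
default stays 500.

## Known limitations

* The morphological tables are for *C. nigripes* at constant temperatures;
  fluctuating-regime PMI reconstruction and accumulated-degree-hour
  conversion are out of scope.
* The whole-body sub-stage scheme (A–L) is carried descriptively only; no
  quantitative whole-body durations are packaged.
* Windows are hard intervals, not posteriors: the package never claims a
  probability that the age lies at a particular point within a window.
* The spectral track's real-data performance cannot be validated here (no
  deposited spectra); the generator-based results bound what the software
  does, not what the chemistry allows.
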