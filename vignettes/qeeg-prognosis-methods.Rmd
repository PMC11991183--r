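---
title: "Quantitative EEG prognosis after cardiac arrest: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG prognosis after cardiac arrest: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(qeegprog)
```

## The problem

Comatose survivors of cardiac arrest are continuously monitored with EEG in
the days after return of spontaneous circulation (ROSC). Clinicians must
judge the neurological prognosis — summarised by the Cerebral Performance
Category (CPC), where CPC 1–2 is a good outcome and CPC 3–5 poor — and that
judgement influences decisions as grave as withdrawal of life-sustaining
therapy. A false prediction of a poor outcome is therefore the costliest
error, which shapes the headline evaluation metric used here: the true
positive rate for predicting *poor* outcome while the false positive rate is
capped at 0.05.

`qeegprog` implements a complete quantitative-EEG pipeline for this problem:
standardisation of multichannel recordings, three hourly feature families,
period aggregation into a fixed named feature space, a feature-selector ×
classifier evaluation harness, the capped-TPR score with per-hospital
evaluation, additive (SHAP) model attributions grouped by electrode distance
and frequency class, and per-hour group-contrast timecourses. Because the
clinical recordings themselves cannot ship with a package, a synthetic
cohort generator with planted, known structure stands in for them; every
stage of the pipeline is tested against that ground truth.

## Preprocessing

Recordings are mapped to the 19-channel 10–20 montage
(Fp1 … Pz, with the T7/T8/P7/P8 aliases translated to T3/T4/T5/T6), filtered
to 0.5–45 Hz, resampled to 256 Hz and average-referenced, in that order.
The filter is a zero-phase Butterworth band-pass: a 2nd-order high-pass at
0.5 Hz and an 8th-order low-pass at 45 Hz. We apply the squared magnitude
response of each filter in the frequency domain over the whole recording,
which is identical to a forward–backward (`filtfilt`) pass up to boundary
handling and keeps 50/60 Hz mains at least 40 dB down. The average reference
makes the cross-channel mean exactly zero at every sample.

Each hour is split into non-overlapping 2 s epochs, and an epoch is rejected
when its maximum peak-to-peak amplitude across channels exceeds 300 µV
(artifact) or falls below 1 µV (flatline); boundary values are kept. If
fewer than 30% of an hour's epochs survive (strict "less than"), every
feature of that hour becomes an explicit null (`NA`) — never a zero. The
same peak-to-peak rule is applied to the 30 s coherence epochs.

## Feature families

Three tensors are computed per patient over 72 hourly bins from ROSC:

* **Band power** (19 × 5 × 72, µV²): Welch power spectral density on each
  2 s epoch (1 s Hann segments, 50% overlap, a 1 Hz grid), integrated over
  delta (0.5–4 Hz), theta (4–8), alpha (8–13), beta (13–30) and gamma
  (30–45), averaged over the kept epochs of the hour. The five bands tile
  0.5–45 Hz, so their sum equals the total power on that range exactly.
* **Functional connectivity** (171 × 5 × 72): magnitude-squared coherence
  (MSC), `|S_xy|² / (S_xx · S_yy)`, for all (19·18)/2 unordered channel
  pairs in fixed lexicographic order. Within each 30 s epoch the spectra are
  averaged over `K` Hann sub-segments with 50% overlap and the per-bin MSC
  is averaged (unweighted) over the bins of each band, then over the hour's
  kept epochs.
* **Burst suppression ratio** (19 × 3 × 72): the fraction of artifact-free
  time each channel's amplitude envelope spends suppressed below 5, 10 and
  15 µV. The envelope is the RMS in sliding 0.25 s windows; a suppressed run
  must persist ≥ 0.5 s and runs separated by < 0.1 s are merged (standard
  aEEG conventions; all exposed in `feature_config()`). Detection runs on
  the continuous hour because suppression is defined by run lengths;
  QC-rejected epochs are masked out of the time base.

### Choosing K for the coherence estimator

MSC estimated from `K` averaged segments carries the classical small-sample
bias, approximately `(1 − C)²/K`, which equals `1/K` for independent
signals. With `K = 8` the bias at a true coherence of 0.25 is ≈ 0.08 — large
enough to swamp the closed-form oracle the synthetic generator provides. We
default to `K = 24` (3672-sample sub-segments of a 30 s epoch at 256 Hz,
≈ 0.42 Hz resolution): measured bias at C = 0.25 is ≈ +0.026, the delta band
still spans ~8 bins, and the independence bias remains ≈ 1/K, which the test
suite asserts at the configured `K`.

## Assembly: the 4028-feature vector

Hourly tensors are averaged over four periods from ROSC — T1 = 0–12 h,
T2 = 12–24 h, T3 = 24–48 h, T4 = 48–72 h — using only non-null hours; a
period with no usable hours is missing. Per period that yields 95 PSD + 855
FC + 57 BSR features, hence 4 × 1007 = 4028 named EEG features
(`PSD_Cz_alpha_T1`, `FC_Cz_Pz_alpha_T2`, `BSR_Cz_15mV_T3`, …). The BSR
names carry the period suffix; without it the 4028 count is unreachable.
Clinical covariates (age, sex, shockable rhythm, OHCA, ROSC time, TTM code)
are appended after the EEG block and are not part of the 4028 count.
Patients with fewer than 5 usable hours are excluded (strictly "less
than"). The positive class is the poor outcome.

Z-score normalisation uses the per-feature mean and *population* standard
deviation learned on training rows only; constant features are flagged and
emitted as zero, and missing values pass through. Median imputation (also
train-fitted) serves the classifiers that cannot ingest missing values;
gradient-boosted trees receive native `NA` markers.

## Models and evaluation

Selectors: an L1-penalised sparse linear selector (features ranked by entry
order along the regularisation path; implemented with `glmnet`'s lasso
logistic regression), random-forest impurity importance (`ranger`), and
gain importance from three gradient-boosted-tree configurations. The three
GBDT variants — depth-wise growth, leaf-wise "lossguide" growth, and shallow
symmetric-style trees (the primary classifier) — are all realised as
`xgboost` configurations, standing in for the three boosting families
commonly compared in this literature. Classifiers additionally include
k-nearest neighbours, logistic regression and an RBF-kernel SVM.

Cross-validation is stratified five-fold at the patient level. Inside every
fold the imputer, normalizer and selector are fitted on the training rows
only; the test suite asserts that corrupting held-out labels cannot change
any fitted state. `grid_search()` tabulates mean capped-TPR scores over
selector × classifier × k cells (k ∈ {25, 75} by default, plus a
no-selection column); `feature_sweep()` scans k = 1…100 and reports the
smallest k whose mean AUROC comes within 0.01 of the full-feature baseline.
`loho_cv()` holds out one hospital at a time, training on the rest.

The capped-TPR ("challenge") score enumerates all achievable thresholds
(midpoints of sorted unique scores; ties share a threshold) and returns the
maximum TPR among those with FPR ≤ 0.05 — an inclusive cap, matching the
published evaluation convention; with 20 negatives exactly one false
positive is allowed. A brute-force threshold enumeration is kept in the test
suite as an oracle. AUROC is the rank statistic (ties count ½), AUPRC is an
interpolation-free step sum, and F1 = 2PR/(P+R) with precision reported as 0
(flagged) when nothing is predicted positive.

## Interpretation

For gradient-boosted models, per-sample additive attributions are exact
tree-path (TreeSHAP) values from `xgboost`; for any other scorer a
fixed-seed permutation-sampling Shapley estimate against the feature-wise
median background is used. Additivity (base value + attributions = output
margin) is asserted in the tests.

Connectivity features are categorised by electrode distance — *short* iff
the two electrodes are adjacent in the 10–20 layout, else *long* — using an
adjacency list that ships as an editable data file
(`extdata/montage_adjacency.csv`: the immediate neighbours along and across
the standard chains; every electrode has at least two neighbours). The
authors of the montage dichotomy never enumerate adjacency, so the list is
a documented, replaceable convention. Bands are classed low (delta, theta)
vs high (beta, gamma), with alpha kept separate because its role in the
dichotomy is genuinely ambiguous.

A feature's direction tendency ("does a high value push toward poor
outcome?") is the sign of the Spearman correlation between feature value
and attribution, with a ±0.1 dead zone — and is *indeterminate* whenever the
feature's mean |attribution| is below 5% of the largest feature's. The
magnitude guard operationalises "attributions distributed around zero":
without it, boosted trees that occasionally split on a noise feature give
that feature a tiny but internally monotone attribution pattern, and a
correlation-only rule would confidently call its direction.

## The synthetic cohort generator

The generator plants exactly the statistical structure the pipeline
measures, with ground truth returned alongside:

* **Band powers** per channel and hour via spectral shaping: white noise is
  masked per band in the FFT domain and scaled so each band's expected
  variance equals its target. Mask edges carry a 0.25 Hz raised-cosine taper
  *inside* the band: a brick-wall edge would give the noise sinc-like
  long-range autocorrelation, making Welch sub-segments dependent and
  visibly biasing segment-averaged coherence, while the taper leaves per-bin
  coherence of co-generated components untouched (all components share the
  mask and coherence is scale-free per bin).
* **Coherent sources**: six disjoint long-distance channel pairs share a
  band-limited source `s` with `x₁ = s + n₁`, `x₂ = a·s + n₂`, giving the
  closed-form in-band MSC `a²σ_s⁴ / ((σ_s²+σ₁²)(a²σ_s²+σ₂²))` that the
  coherence estimator is tested against (0.25 in the all-unit-variance
  case). Disjointness keeps the closed form exact per pair.
* **Burst suppression**: an alternating two-state renewal process with
  exponential durations (memoryless — the simplest generative choice; the
  source literature specifies none). The suppression mean solves the
  requested long-run occupancy; during suppression all channels are scaled
  by 0.02 so the envelope falls below the lowest threshold. The sampled
  state sequence is returned as truth. Estimator-recovery tests use 6 s mean
  bursts: the ≥ 0.5 s minimum-duration convention censors runs that are
  short relative to the detector dead-time, which is a property of every
  BSR definition with a minimum suppression duration, not an estimator
  defect; long states isolate occupancy recovery from duration censoring.
* **Artifacts**: 2 s-aligned segments replaced by > 300 µV excursions or
  near-flat stretches, with the per-epoch mask as truth.
* **Group profiles** follow the contrasts reported for real post-arrest
  cohorts. Good outcome: higher broadband power with a theta rise peaking
  near 20 h, suppression occupancy decaying quickly to ~10%. Poor outcome:
  globally weaker, low-frequency-dominant power, elevated delta-band
  long-distance coherence (≈ 0.55 vs ≈ 0.10), occupancy staying above ~20%
  with a late rise, older age, fewer shockable rhythms. Crucially, the
  per-patient amplitude scale and band mix vary several-fold (log-normal
  jitters), so band power and BSR overlap heavily between groups while the
  planted coherence contrast stays crisp — mirroring cohorts in which
  connectivity dominates model attributions and raw power contributes
  little. The amplitude-scale jitter is truncated (×0.45–×1.6) so that no
  patient's EEG leaves the 1–300 µV peak-to-peak QC window wholesale —
  untruncated tails would have entire hours rejected, and that attrition
  would correlate with outcome. Hospitals are assigned uniformly and
  independently of outcome.

What the generator does *not* emulate: physiological EEG morphology
(spindles, seizures, reactivity), volume-conduction correlation structure
between neighbouring electrodes, non-stationary artifact types, or any
dependence of label noise on covariates. Passing tests therefore demonstrate
that the pipeline recovers known planted structure — not that it attains any
particular performance on real patients.

## Problem sizes and numerical choices

The generator's "hour" is configurable in seconds (`hour_s`): a real-data
hour is 3600 s (1800 2 s epochs, 120 30 s epochs — the structural counts the
tests assert at full scale), while cohort-level experiments in the tests and
the acceptance script use 120 s hours at 128 Hz, 12 h per patient and 100
patients. The per-hour feature definitions are unchanged under this
compression; only the number of epochs averaged per hour shrinks. Estimator
oracles run at full hour length. Classifier defaults are the library
defaults with capped tree counts (200–300 rounds) and fixed seeds;
every randomised routine takes an explicit seed and fixed seeds reproduce
cohorts and cross-validation results bit-for-bit.

Other numerical conventions: thresholds at midpoints between unique scores
with ±∞ sentinels; Welch one-sided PSD with Hann windows and 50% overlap;
coherence of a zero-variance signal is undefined and returns `NA` with a
warning; the "paired t-test" wording used for group timecourses in parts of
this literature is implemented as Welch's two-sample t-test (the groups are
independent patients), with a pooled-variance variant and optional
Benjamini–Hochberg adjustment behind flags (no adjustment by default).

## Interfaces

This is an analysis package: the exported functions and this vignette are
the interface, and `scripts/acceptance.R` is the one runnable entry point
(it regenerates every quantity the package claims, from scratch, into a
JSON report). Cohorts can be written to and read back from WFDB-style
header + 16-bit signal files with I-CARE-style plain-text metadata sidecars
(`write_cohort()`, `read_record()`); no WFDB implementation exists in the
dependency stack, so the subset needed here is implemented in the package.

## Known limitations

* The MSC estimator is reported raw, with its `(1−C)²/K` bias; debiasing is
  deliberately not applied so that values remain comparable with the
  standard definition.
* BSR at a fixed voltage threshold conflates suppression with low-amplitude
  EEG; patients with globally low amplitude read as high BSR. This is a
  property of the definition and is reproduced faithfully.
* The L1 selector is an L1-penalised logistic regression rather than a
  linear SVM (no sparse linear-SVM implementation is available in the
  dependency stack); both are sparse linear margin methods and the selector
  contract (entry-order ranking, determinism) is unchanged.
* Only three GBDT parameterisations of one library stand in for three
  distinct boosting families.
* Synthetic validation bounds what can be claimed about real recordings;
  see the generator section above.
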