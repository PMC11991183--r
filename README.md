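# qeegprog

Quantitative-EEG biomarkers and prognostic modelling for comatose patients
after cardiac arrest.

Survivors of cardiac arrest are continuously EEG-monitored in the ICU while
clinicians judge their chance of neurological recovery (Cerebral Performance
Category: CPC 1–2 good, CPC 3–5 poor). `qeegprog` implements a complete,
tested pipeline for that problem, aimed at researchers in clinical
neurophysiology and ML for critical care:

* **Ingest** — WFDB-style continuous EEG with plain-text clinical sidecars
  (age, sex, ROSC, OHCA, shockable rhythm, TTM, CPC, hospital); mapping to
  the 19-channel 10–20 montage, zero-phase 0.5–45 Hz Butterworth band-pass,
  resampling to 256 Hz, average reference; 2 s epoching with peak-to-peak
  rejection (kept iff 1 µV ≤ max-channel p2p ≤ 300 µV) and a 30% per-hour
  retention gate.
* **Features** — three hourly tensors per patient over 72 h from ROSC:
  Welch band power (19 ch × 5 bands: δ 0.5–4, θ 4–8, α 8–13, β 13–30,
  γ 30–45 Hz), magnitude-squared coherence
  `C_xy(f) = |S_xy(f)|² / (S_xx(f)·S_yy(f))` for all 171 channel pairs from
  30 s epochs, and burst suppression ratio at 5/10/15 µV envelope
  thresholds.
* **Assembly** — aggregation over four periods (T1 = 0–12, T2 = 12–24,
  T3 = 24–48, T4 = 48–72 h) into a named 4028-dimensional EEG feature
  vector plus clinical covariates; a ≥ 5 h usability filter; leakage-safe
  z-scoring `z = (x − µ)/σ` with the population σ learned on training rows
  only.
* **Models** — a selector × classifier harness (L1 sparse-linear,
  random-forest and three gradient-boosting importance selectors; RF, kNN,
  logistic, RBF-SVM and three GBDT classifier configurations), stratified
  five-fold CV with in-fold selection, a 1–100 feature-count sweep with the
  "< 0.01 AUROC difference" rule, and leave-one-hospital-out evaluation.
* **Metrics** — the capped-TPR score (maximum TPR for predicting *poor*
  outcome subject to FPR ≤ 0.05 — the clinically motivated headline metric),
  AUROC, AUPRC, F1.
* **Interpret** — exact TreeSHAP attributions for the boosted models (a
  sampling fallback otherwise), aggregated by feature family, electrode
  distance class (short = adjacent in the 10–20 layout), frequency class
  (low δ/θ vs high β/γ, α separate) and period, with per-feature direction
  tendencies.
* **Timecourse** — per-hour Welch group contrasts and period-restricted
  models (single periods, unions, later-minus-earlier differences).
* **Synthetic cohorts** — `generate_cohort()` plants known band-power
  trajectories, pairwise coherent sources with a closed-form coherence
  oracle, a two-state burst/suppression process with known occupancy,
  artifacts, hospitals and CPC labels, so every stage is verifiable without
  clinical data.

## Worked example

A 40-patient synthetic cohort (12 h per patient, compressed 120 s hour bins
at 128 Hz), end to end from signals to a cross-validated model and its
attribution summary:

```r
library(qeegprog)

cfg    <- cohort_config(n_patients = 40, fs = 128, duration_h = 12,
                        hour_s = 120, seed = 42, good_fraction = 0.4)
cohort <- generate_cohort(cfg)

fcfg    <- feature_config(fs_target = 128, hour_s = 120)
tensors <- lapply(cohort$records, extract_patient, cfg = fcfg)
dm      <- build_design_matrix(filter_patients(tensors))

cv <- run_cv(dm$X, dm$y, classifier_spec("gbdt_c", seed = 1),
             folds = 5, seed = 1)
round(cv$mean, 3)
#> challenge_score           auroc           auprc              f1
#>           0.840           0.933           0.964           0.892

model <- fit_classifier(classifier_spec("gbdt_c", seed = 1), dm$X, dm$y)
at    <- attribute(model, dm$X)
category_summary(at)
#>     family mean_attr mean_abs_attr  share
#> 3       FC  0.000136      0.000719 0.5423
#> 4      PSD  0.000288      0.004776 0.4004
#> 2 clinical  0.000187      0.043251 0.0572
#> 1      BSR  0.000000      0.000000 0.0000
```

Reading the numbers: the cross-validated AUROC (0.933) says the model
separates the planted poor-outcome structure well, and the capped-TPR score
(0.840) is the fraction of poor-outcome patients caught while mispredicting
at most 5% of the good-outcome patients — the error that matters most
clinically. The attribution shares recover what the generator planted:
functional connectivity (FC) carries the largest share of the model's
output, and its top feature is the planted low-frequency long-distance pair
with a *positive* tendency (higher delta coherence between distant
electrodes → poor outcome), while high-frequency band power tends negative
(toward good outcome):

```r
merge(top_attributions(at, k = 3)[, c("feature", "family")],
      direction_tendency(at), by = "feature")
#>              feature   family   rho tendency
#> 1 FC_Fp1_O1_delta_T1       FC  0.86 positive
#> 2    PSD_F3_gamma_T1      PSD -0.86 negative
#> 3               rosc clinical  0.75 positive
```

Cohorts round-trip through WFDB-style files with `write_cohort()` /
`read_record()`. See the methods vignette
(`vignettes/qeeg-prognosis-methods.Rmd`) for the model details, parameter
defaults and the generator's design.

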