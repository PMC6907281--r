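---
title: "Quantitative EEG outcome prediction after severe traumatic brain injury: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG outcome prediction after severe TBI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Patients with moderate-to-severe traumatic brain injury (TBI, Glasgow Coma
Scale ≤ 12) are monitored for days in the ICU, often sedated, while
clinicians must form an early prognosis. Admission-based predictors (the
IMPACT parameter set: age, GCS motor score, pupillary reactivity, Marshall
CT class, epidural hematoma, traumatic subarachnoid hemorrhage,
hypotension, hypoxia, glucose, hemoglobin) ignore everything that happens
after admission — secondary injury, treatment effects. Continuous EEG is a
bedside window on cortical function throughout that period. `qeegpredict`
implements a full pipeline from raw 19-channel EDF recordings to a
Random-Forest classifier of 12-month outcome (Extended Glasgow Outcome
Scale, GOSE), fusing quantitative EEG (qEEG) features with age, mean
arterial pressure (MAP) and the IMPACT covariates.

Outcome is dichotomized as poor = GOSE 1–2 vs good = 3–8 (primary), or
poor = GOSE 1–4 (secondary); `dichotomize_gose()` implements both.

## Signal path

1. **Ingestion** (`read_edf`): standard 16-bit EDF; the 19 electrodes of
   the 10–20 system are required and label matching is tolerant of common
   dialects ("EEG Fp1-REF", T7/T8/P7/P8 synonyms). Samples are converted
   to microvolts; recordings at other rates are polyphase-resampled to
   256 Hz so every 10-s epoch is exactly 2560 samples. The recording is
   placed on a trauma-relative timebase from the trauma timestamp.
2. **Filtering** (`bandpass`): zero-phase Butterworth 0.5–30 Hz — a
   3rd-order design run forward and backward, i.e. a 6th-order zero-phase
   magnitude response with no group delay. Filtering is linear, so it is
   applied once to the 19 channels per 60-min segment, before slicing;
   both derived montages inherit it, and filter edge transients stay out
   of the analysis windows.
3. **Windowing** (`slice_windows`): at 24, 48, 72 and 96 h post-trauma the
   60-min segment starting at the hour is cut into six contiguous 10-min
   windows. If the hour is not fully covered the pipeline tries −1, +1,
   −2, +2 h, in that order, and records the shift used. Earlier hours are
   preferred on ties so a feature never borrows from strictly later
   physiology when an earlier complete hour exists; only fully covered
   hours qualify, which keeps the six-windows-per-interval structure
   exact. The segment starts at the hour boundary (centring on the hour
   would be an equally defensible convention; one had to be fixed).
4. **Artifact screening** (`detect_artifacts`): per 10-s epoch and channel
   in the common-average reference, a channel is rejected when any sample
   reaches ±150 µV, when the epoch variance reaches 1400 µV² (movement /
   noise), or falls to ≤ 1 µV² (empty channel). Variance is the population
   variance of the mean-removed epoch, so a constant channel scores
   exactly 0. Thresholds are applied to the filtered signal. Epochs with
   fewer than 9 of 19 clean electrodes are dropped wholly — global
   features (symmetry, coherence, topography) are meaningless on very
   sparse montages. All thresholds are configurable
   (`preprocess_config`).
5. **Mask mapping** (`apply_mask`): features are computed in the
   longitudinal-bipolar ("double banana") montage while screening runs in
   common average, so electrode-level rejections are propagated to both
   bipolar derivations touching the electrode: a contaminated electrode
   corrupts every derivation it feeds. Retained samples are never altered
   (rejection, not correction).

## The 23 features (`extract_features`)

Spectral quantities come from Welch periodograms of the 10-s epochs: 4-s
Hamming-tapered segments at 50% overlap (0.25 Hz resolution — enough to
resolve the 0.5 Hz band edge, and consistent with the 4-s/50% settings of
the coherence estimator). Band edges: delta 0.5–4, theta 4–8, alpha 8–13,
beta 13–20 Hz; total power 0.5–20 Hz. Band integrals use the trapezoidal
rule on each closed band interval; neighbouring bands share each edge's
half-trapezoid, so the four band powers sum *exactly* to the total and
the relative powers to 1. Within a window, derivations are averaged
within each epoch first, then across epochs.

| feature | definition | unit / range |
|---|---|---|
| `abs_{delta,theta,alpha,beta}` | band-integrated PSD, derivation-averaged | µV² |
| `total_power` | sum of the four band powers | µV² |
| `rel_*` | band / total | fraction, sums to 1 |
| `adr` | alpha / delta power ratio | ratio (NA if delta = 0) |
| `sef90` | frequency below which 90% of 0.5–20 Hz power lies, linearly interpolated | Hz |
| `var_*` | MAD / median of the 60 per-epoch band powers, clipped to [0,1]; needs ≥ 8 valid epochs | [0,1] |
| `bsi_total`, `bsi_delta` | mean over 8 homologous left/right derivation pairs and frequencies of \|(R−L)/(R+L)\|; midline excluded | [0,1] |
| `cog_x`, `cog_y` | power-weighted centroid of electrode positions (unit disc, x: left→right, y: posterior→anterior), per-electrode total power from the common-average montage | [−1,1] |
| `mean_amplitude` | standard deviation of the signal per derivation per epoch, averaged | µV |
| `coherence` | mean magnitude-squared coherence over all derivation pairs, 4-s Hann segments, 2-s overlap, full 10 min, averaged over 0.5–20 Hz | [0,1] |
| `shannon_entropy` | entropy of the amplitude histogram, 100 fixed bins over ±150 µV | bits |
| `regularity` | continuity of the squared, 0.5-s-smoothed amplitude: with sorted values q₁ ≥ … ≥ q_N, √(Σ i²qᵢ / ((N²/3) Σ qᵢ)) | [0,1] |

Notes on deliberate choices:

* **SEF90** is computed on the 0.5–20 Hz total-power range, not up to the
  30 Hz filter edge, so it is consistent with the band scheme.
* **Variability** uses the unscaled MAD (no 1.4826 normal-consistency
  factor) and is clipped: heavy-tailed epoch-power series can push
  MAD/median above 1, but the measure is defined on [0,1].
* **COG** needs electrode-resolved power, which bipolar derivations
  cannot give, so it is the one feature computed from the common-average
  montage; only the total band is used (per-band centroids would break
  the count of 23). The coordinate table is left/right and
  anterior/posterior symmetric, so uniform power maps to (0, 0).
* **Entropy** uses fixed bins over the artifact-clean range so values are
  comparable across windows; out-of-range samples (possible in bipolar
  derivations, which can exceed single-electrode bounds) are counted in
  the edge bins.
* **Regularity** follows the standard continuity operationalization for
  ICU EEG; a constant-amplitude signal gives ≈ 1 (the discrete sum
  slightly exceeds N³/3, hence the clip), burst-suppression-like signals
  fall well below 0.5.
* **Coherence** is estimated on the full 10 min per pair rather than per
  epoch: 4-s segments in a 10-s epoch would give 4 segments and a
  heavily biased magnitude-squared coherence; ~300 segments make the
  estimator stable. A segment counts for a pair only when it lies in
  epochs valid for both derivations.
* **Missingness**: any feature that cannot be computed is NA; windows
  reach the model only when complete (the Random-Forest stage excludes
  observations with missing data).

## Clinical fusion and observation tables (`assemble`)

Each usable window contributes one observation: the 23 features, the MAP
for the window's hour, and age; optionally the nine non-age IMPACT
columns (ordinal-coded: pupils 0/1/2, Marshall 1–6, binaries 0/1 —
Random Forests are invariant to monotone coding; glucose mmol/L,
hemoglobin g/dL, validated but never converted). Two-interval models pair
window *k* of one interval with window *k* of the other (≤ 6 rows per
patient, never the 36-way cross product, keeping per-patient observation
counts equal across model variants). MAP entries are hourly spot checks
whose timestamps rarely align with the hour grid, so an entry belongs to
the EEG's hour when it lies within half an hour of that segment; with no
entry there, the nearest within 2 h is used, else the row is incomplete
and dropped (listwise deletion, with a logged count).

## Model and evaluation (`fit_rf`, `lopo`, `run_protocol`)

The classifier is a Breiman Random Forest (package `randomForest`):
100 trees, at most 20 terminal nodes, √p candidate features per split.
Two evaluation choices deserve emphasis:

* **Class-balanced bootstrap.** Each tree is grown on a bootstrap drawn
  with equal counts from both classes (`strata`/`sampsize`). Without
  this, leave-one-patient-out has a subtle pathology: removing a patient
  tilts the training prior against that patient's class, and when
  features carry little signal the vote fractions track the prior, which
  *anti-ranks* every held-out patient and collapses the null AUC far
  below 0.5. Balanced sampling restores chance-level calibration under
  label exchangeability (verified by the null-cohort acceptance test)
  and is standard practice for the mildly imbalanced cohorts this
  models.
* **Patient-level scoring.** Training operates on window-level
  observations, but performance is patient-level: a patient's score is
  the mean poor-outcome vote fraction over their held-out windows, the
  natural pooling of forest votes.

Leave-one-patient-out keeps all of a patient's windows together; the ROC
(poor = positive) is computed over patient scores with `pROC`. The 50%
confidence interval is a 2000-resample patient-level bootstrap
(25th–75th AUC percentiles). The operating threshold maximizes Youden's
J; ties go to the higher specificity. Importances are normalized mean
decrease in impurity from a single fit on the full table (an alternative
would average importances over the LOPO fits; the full-table fit is
simpler and uses identical data).

`run_protocol` reproduces the three-stage design: (1) full-feature
models on the 4 single intervals and all 6 two-interval pairs; (2) each
refit on its top-10 features; (3) top-10 + the nine IMPACT parameters —
so a stage-3 model whose top-10 contains one MAP and age has exactly 19
modelled columns. Feature selection operates on all columns (age and MAP
compete with the qEEG features and can be dropped). `validate_model`
scores a held-out cohort with a forest trained once on the full training
table only.

## The synthetic cohort generator (`cohort_spec`, `simulate_eeg`)

No public TBI cEEG dataset with these covariates exists, so the package
ships a generator that emulates exactly the statistical structure the
features measure — band-limited Gaussian processes (spectrally shaped
noise) plus a 1/f background, rather than a neural-mass model, because
shaped noise puts the spectral quantities under exact analytic control.
Outcome conditioning (defaults; directions follow the clinical
literature, magnitudes are calibration choices for a clearly separable
cohort, not claims about TBI):

* overall amplitude ratio poor/good **0.5** (good-group mean band SDs
  delta/theta/alpha/beta = 8/4.5/7.5/2.5 µV + 3.5 µV 1/f floor, ~13 µV
  total — ICU-plausible and, with the per-patient cap at 20 µV,
  comfortably below the artifact thresholds even in high-modulation
  epochs);
* per-patient heterogeneity, identical in distribution in both groups
  (so null cohorts remain exchangeable): lognormal overall scale (log-sd
  0.20, capped at 20 µV channel SD), variance-preserving band
  composition jitter (log-sd 1.2 — it reshuffles power across bands
  without touching the total), asymmetry jitter (log-sd 0.5),
  modulation-depth jitter (sd 0.35), and a burst-attenuation
  *continuity* parameter (0.45–0.97): 0.5-s blocks are attenuated to
  15% amplitude with probability 1 − continuity, normalized to unit mean
  square — emulating the discontinuous background common after severe
  TBI, which decouples entropy and regularity from pure signal scale.
  Without heterogeneity every spectral feature would separate the groups
  perfectly and importance rankings would be arbitrary;
* additional alpha suppression ×**0.3** in the poor group;
* right-hemisphere gain **0.6** (poor) vs 1.0 (good) — drives the
  symmetry index;
* epoch-wise amplitude modulation depth **0.4** (good) vs **0.1** (poor)
  — drives the variability features;
* ~1 artifact epoch per 10-min window (flat epochs and ±200–400 µV
  transients), placements recorded in a ground-truth sidecar;
* age N(58, 12) poor vs N(38, 14) good (truncated at 18), admission
  glucose +2 mmol/L and MAP −10 mmHg in the poor group, and
  outcome-tilted motor/pupil/CT/laboratory priors.

`null_cohort_spec()` equalizes every outcome-conditioned parameter, so
labels are exchangeable by construction — the basis of the calibration
tests. Determinism: every patient/recording seed derives from the cohort
seed, and identical specs reproduce byte-identical EDF and CSV outputs.

What the generator does **not** emulate: sleep transients, seizures,
sedation pharmacology, non-stationary drift, volume-conduction
correlation structure between electrodes (channels are independent given
the group parameters), or realistic between-patient heterogeneity within
an outcome group. Passing tests therefore demonstrate that the pipeline
recovers the *encoded* structure faithfully — not that these effect
sizes, or the resulting AUCs, transfer to real TBI cohorts.

## Experiment sizes

Simulating a 19-channel hour at 256 Hz costs ~17 M samples, so the
package's standing experiments use desk-scale cohorts:

* *Signal recovery*: 12 patients (6/6), intervals 72 + 96 h — stage-3
  leave-one-patient-out AUC and importance ranking; ranking stability is
  assessed across 5 forest seeds.
* *Null calibration*: 40 patients (20/20), interval 72 h, one
  EEG-level null cohort and 20 patient-level label permutations — under
  exchangeability a permutation is distributed identically to
  regenerating the cohort, at a fraction of the cost.
* *Protocol bookkeeping* is exercised on feature-level synthetic tables
  (the bookkeeping does not depend on how features were obtained).

### A structural note on importance rankings

Three of the 23 features are mathematically entangled: total power is
(essentially) the square of the mean amplitude, and for near-Gaussian
signals the fixed-bin Shannon entropy is close to a monotone transform
of the amplitude as well. Random-Forest impurity importance splits
credit arbitrarily among monotone-equivalent features, so when the
amplitude effect dominates a cohort, the top of the ranking fills with
this family (mean amplitude, total power, entropy, per interval) and
undiluted single covariates such as age are crowded out — even when age
separates the groups well on its own. The burst-attenuation continuity
parameter partly decouples entropy, but total power remains a clone by
construction. The recovery experiment therefore checks mean amplitude's
presence in the top ranks (robust) separately from age's (sensitive to
this credit-sharing, and not robust at desk-scale cohort sizes); a
permutation importance would be the principled alternative for real
analyses.

## Known limitations

* The external IMPACT logistic-regression predictor (an online
  comparator in the original study design) is out of scope; report
  schemas leave room for externally computed IMPACT probabilities.
* EDF support is deliberately minimal: standard 16-bit EDF, no EDF+
  annotations or discontinuous records.
* Gini importances are biased toward continuous features; with 9 of the
  19 stage-3 columns ordinal/binary this flatters the qEEG features
  slightly. Permutation importance would be the alternative.
* A 50% confidence interval is unusually narrow for reporting; it is
  retained because the three-stage protocol compares models by it.
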