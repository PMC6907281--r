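# qeegpredict

Outcome prognostication for moderate-to-severe traumatic brain injury
(TBI) from continuous ICU EEG. The package implements a complete,
tested pipeline: standard-EDF ingestion with 10–20 montage validation,
zero-phase 0.5–30 Hz filtering, per-epoch amplitude/variance artifact
screening in the common-average reference, extraction of 23
quantitative EEG (qEEG) features per 10-min window in the
longitudinal-bipolar montage, fusion with age, mean arterial pressure
(MAP) and the ten IMPACT admission parameters, and a Random-Forest
classifier of 12-month outcome (Extended Glasgow Outcome Scale,
GOSE 1–2 vs 3–8, or 1–4 vs 5–8) evaluated by leave-one-patient-out
(LOPO) with patient-level ROC/AUC, 50% confidence intervals, operating
threshold and feature importances.

**Who it is for:** clinical-neurophysiology and critical-care
researchers building multimodal prognostic models from continuous EEG,
and methodologists who need a fully synthetic, ground-truth-controlled
EEG cohort to validate such pipelines end to end.

## The model in brief

Per patient, the 60-min segments at 24, 48, 72 and 96 h post-trauma
(with ±1 h/±2 h fallback) are cut into six 10-min windows. Each window
yields 23 features: absolute and relative band powers (δ 0.5–4, θ 4–8,
α 8–13, β 13–20 Hz; Welch, 4-s Hamming segments, 50% overlap), total
power (0.5–20 Hz), the α/δ ratio, the 90% spectral edge frequency,
per-band variability (MAD/median of per-epoch band powers), the
pairwise brain symmetry index `mean |(R−L)/(R+L)|` over homologous
bipolar pairs (total and δ ranges), the power-topography centre of
gravity (x, y), mean amplitude (signal SD, µV), mean magnitude-squared
coherence over all derivation pairs (4-s Hann, 2-s overlap), Shannon
entropy of the amplitude histogram, and a continuity/regularity index.
Windows become observations (features + MAP + age, optionally + 9
IMPACT covariates); a 100-tree Breiman Random Forest capped at 20
terminal nodes with class-balanced bootstrap is evaluated LOPO, scoring
each held-out patient by their mean poor-outcome vote fraction. A
three-stage protocol fits all single/paired intervals, refits on the
top-10 impurity-ranked features, then augments with the IMPACT
parameters. Since no public dataset with these covariates exists, an
outcome-conditioned synthetic cohort generator (band-limited Gaussian
processes with per-patient heterogeneity, asymmetry, amplitude
modulation, burst-attenuation and injected artifacts) stands in for
patient recordings; see the methods vignette
(`vignettes/qeeg-outcome-prediction.Rmd`) for every modelling choice.

## Worked example

Simulate a 6-patient cohort, extract features and evaluate LOPO at the
72-h interval:

```r
library(qeegpredict)

spec <- cohort_spec(n_poor = 3, n_good = 3, seed = 42)
ch   <- simulate_cohort_features(spec, intervals = 72)

head(ch$features[, c("patient_id", "window_index", "rel_alpha",
                     "mean_amplitude", "bsi_total", "sef90")], 4)
#>  patient_id window_index rel_alpha mean_amplitude bsi_total sef90
#>        P001            1     0.015          9.410     0.037 4.275
#>        P001            2     0.015          9.286     0.037 4.330
#>        P001            3     0.015          9.411     0.038 4.248
#>        P001            4     0.015          9.388     0.037 4.323

tab <- assemble(ch$features, ch$clinical, ch$map, intervals = 72)
lopo(tab, model_config(seed = 1))
#> <evaluation_report> 6 patients, 36 observations
#>   AUC 1.000 (50% CI 1.000-1.000); threshold 0.497, sens 1.00, spec 1.00
#>   top importances: map, abs_alpha, mean_amplitude, age, shannon_entropy
```

Patient P001 has poor outcome: suppressed relative alpha (0.015), low
mean amplitude (~9 µV) and a low spectral edge — the generator's
encoded severity signature — and the forest separates the groups
perfectly on this small, strongly-conditioned cohort (AUC 1.0 with
sensitivity and specificity 1.0 at the Youden-optimal vote threshold
0.497). `run_protocol()` runs the full three-stage model comparison,
and `run_pipeline(run_config(...))` drives the same computation from
EDF files and clinical CSVs on disk (see `inst/cli/qeegpredict.R` for
the shell entry point).

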