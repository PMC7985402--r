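# spectralforest

Transdiagnostic prediction of cognitive test performance from resting-state
EEG power spectra, with honest out-of-bag evaluation and permutation-based
inference.

## The problem

Resting-state EEG power differs between psychiatric cases and controls, but
the differences are variable within disorders and not diagnostically
specific. A more productive question is *which* features of the power
spectrum — which frequencies, at which electrodes — carry information about
specific domains of cognitive functioning, across diagnoses. Answering it
honestly requires (a) a predictive model over the full channel × frequency
feature space rather than preselected bands, (b) a generalization estimate
that does not reuse training data, and (c) significance testing that
respects the high-dimensional, correlated feature space.

`spectralforest` is that pipeline, for researchers in clinical
neurophysiology and machine-learning biostatistics:

* **Spectral features** — Welch-averaged, Hann-windowed periodograms binned
  into 1-Hz bins (1–50 Hz), natural-log transformed, per-feature
  residualized on age and gender: a subjects × (channels × 50) table,
  3200 predictors for a 64-channel 10/10 montage.
* **Random forest with OOB evaluation** — bagged CART regression trees
  (reference configuration: 20,000 trees, 12 predictors sampled per split),
  written in C++ with a deterministic, R-reproducible RNG. Model fit is the
  Nash–Sutcliffe efficiency of the out-of-bag predictions,

  NSE = 1 − Σ(Yₘ − Yₚ)² / Σ(Yₘ − Ȳ)²  ∈ (−∞, 1].

* **Permutation-null inference** — the outcome is shuffled and the forest
  refit (2,000 permutations in the reference design); p is the fraction of
  null NSE values at or above the observed one, tested against a Bonferroni
  threshold (0.05/7 = 0.00714 for seven cognitive tests).
* **Importance profiling** — OOB permutation importance, averaged across
  electrodes into a frequency profile; peaks (local maxima more than 1 SD
  above the profile mean) are mapped back to scalp topographies, and the
  top three channels per peak get signed standardized univariate betas for
  the direction of effect.
* **Clinical follow-ups** — Welch's heteroscedastic ANOVA across diagnostic
  groups (n > 10), Pearson correlations with five symptom dimensions, and
  one-vs-rest diagnosis-prediction control forests.
* **Synthetic cohorts** — a generator of EEG-like data (1/f background,
  band-limited oscillators with scalp topographies, planted
  outcome couplings, covariate effects, EEG-independent diagnosis labels)
  with exported ground-truth latents, so every stage of the pipeline can be
  validated against a known truth.

## A worked example

Simulate a 120-subject cohort whose paired-associates-learning error score
is negatively coupled to a 6 Hz (theta) oscillator peaking at F4, then run
the pipeline:

```r
library(spectralforest)

m <- montage_1010()
osc <- oscillator_spec("theta6", center_frequency = 6, bandwidth = 2,
                       mean_log_power = 2, between_subject_sd = 1,
                       topography = topo_gaussian(m, "F4", width = 0.6))
spec <- cohort_spec(
  n_subjects = 120, montage = m, duration = 60,
  oscillators = list(osc),
  couplings = list(effect_spec("pal_errors", "theta6",
                               slope = -1, noise_sd = 1.5)),
  seed = 42
)
cohort <- simulate_feature_cohort(spec)

res <- fit_residualize(cohort$features,
                       cohort$subjects$age, cohort$subjects$gender)
cfg <- forest_config(n_trees = 500, mtry = 12, seed = 42)
forest <- fit_forest(res$features, cohort$subjects$pal_errors, cfg)
forest
#> <spectral_forest>  120 subjects, 3200 features, 500 trees (mtry 12)
#>   OOB NSE: 0.0603   (min trees OOB per subject: 144)
#>   top importance: C6_6Hz

pt <- permutation_test(res$features, cohort$subjects$pal_errors, cfg,
                       n_permutations = 200, seed = 42, forest = forest)
pt
#> <permutation_null>  observed NSE 0.0603, 0/200 null values >= observed, p = < 0.005

peaks <- find_peaks(frequency_profile(forest))
peaks
#> [1]  5  7 37 48
direction_of_effect(res$features, cohort$subjects$pal_errors, forest, peaks[1])
#> # A tibble: 3 × 5
#>    freq channel importance   beta   p_value
#>   <dbl> <chr>        <dbl>  <dbl>     <dbl>
#> 1     5 T8          0.0789 -0.114 0.215
#> 2     5 Fp2         0.0785 -0.350 0.0000889
#> 3     5 PO4         0.0773 -0.127 0.167
```

Reading the output: the forest explains a modest share of variance in the
error score (OOB NSE 0.06 — small positive values are the realistic regime
for brain–behaviour prediction), yet no outcome shuffle among 200 matched
it, so p < 1/200, far below the 0.00714 threshold. The importance profile
peaks next to the planted 6 Hz oscillator (desk-scale ensembles put the
local maximum at 5 and 7 Hz here; larger ensembles sharpen the profile),
and the top-channel betas are negative — more theta power, fewer errors —
recovering the planted direction of effect. The spurious high-frequency
peaks (37, 48 Hz) have no consistent direction and illustrate why the
design follows peaks up with univariate effects rather than trusting the
importance map alone.

`run_pipeline(pipeline_config(...))` executes the same steps (plus the
clinical follow-ups) from CSV inputs to JSON/CSV reports with a
reproducibility manifest; `autoplot()` on a permutation test,
`plot_frequency_profile()` and `plot_topography()` draw the standard
figures; `tidy()`/`glance()` give tabular summaries of fitted objects.

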