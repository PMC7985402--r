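---
title: "Predicting cognition from resting-state EEG spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cognition from resting-state EEG spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

`spectralforest` implements a transdiagnostic analysis that asks which
features of the resting-state EEG power spectrum carry information about
cognitive test performance, without committing to a priori frequency bands
or electrodes. Eyes-closed multichannel EEG is reduced to a subject ×
(channel × 1-Hz-bin) table of log band powers, corrected for age and gender
by per-feature linear regression. A random-forest regression predicts each
cognitive score from all features at once; out-of-bag (OOB) predictions give
an honest generalization estimate summarized by the Nash–Sutcliffe
efficiency (NSE). Whether a model beats chance is decided by an
outcome-permutation null distribution of the NSE, Bonferroni-corrected over
the number of cognitive tests. For models that beat chance, OOB permutation
importance is profiled over frequency (averaged across electrodes), peaks
are selected, and the top channels at each peak are followed up with signed
univariate standardized regressions to establish the direction of effect.
Group- and dimension-level follow-ups (Welch's ANOVA across diagnoses,
symptom-dimension correlations, diagnosis-prediction control forests)
complete the picture.

## Spectral features

A recording is cut into Hann-windowed segments of 512 samples (1 s at the
512 Hz sampling rate), with 50% overlap between consecutive segments;
per-segment periodograms are averaged (Welch's method), binned into 1-Hz
bins, and natural-log transformed.

Numerical choices worth knowing:

* **Bin convention.** Bin *b* (*b* = 1..50) covers the half-open interval
  \[*b* − 0.5, *b* + 0.5) Hz, so the 1–50 Hz analysis band partitions
  \[0.5, 50.5) with no line dropped or double-counted. With the default
  window the native resolution is exactly 1 Hz and each bin holds a single
  FFT line.
* **Scaling.** Bin powers are scaled so they sum to the window-gain-corrected
  mean square of the segment (a Parseval identity that the tests check to
  1e-6), i.e. the units are µV² per bin.
* **Windowing.** A Hann-windowed tone at a bin centre necessarily leaks:
  the kernel spreads the line over three bins with power weights
  (1/6, 2/3, 1/6). Tests assert this exact concentration rather than a
  no-leakage idealization.
* **Overlap** is configurable (the segmentation scheme of the upstream
  artifact-cleaning pipeline is not part of this package); 50% is the
  standard Welch choice and the default.
* **Log floor.** Powers are floored at 1e-20 before the log so degenerate
  all-zero synthetic channels yield finite features instead of −Inf.
* **Log base.** Natural log. Any other base rescales every column by a
  constant, which is irrelevant to rank-based tree splits and to
  standardized regression coefficients.

## Covariate residualization

Power features are regressed on `[1, age, gender]` across the whole sample
(one OLS fit per feature, QR-based), and residuals replace the values;
coefficients are kept so new subjects can be residualized with frozen
coefficients. Gender is a 0/1 indicator; flipping the coding flips only the
gender slope's sign and leaves residuals untouched. A constant covariate
(single-gender cohort) is dropped with a warning rather than producing a
rank-deficient fit. Cognitive scores enter the *forest* raw — only the
features are residualized — while the group-difference ANOVA uses
residualized scores; this asymmetry is deliberate and mirrors the analysis
design the package implements.

## The forest

The ensemble is bagged CART regression trees, written in C++ for this
package:

* bootstrap of n subjects with replacement per tree;
* at every split, `mtry` candidate features drawn without replacement
  (per split, not per tree — the standard random-forest choice);
* exact variance-reduction split search: candidate thresholds are midpoints
  between consecutive distinct member values with at least `min_leaf`
  instances on each side;
* trees grown deep, `min_leaf = 5` (the conventional regression default);
* OOB prediction: each subject's prediction averages the trees whose
  bootstrap excluded that subject; a subject OOB in zero trees is an error
  instructing a larger ensemble.

The reference configuration is 20,000 trees and `mtry = 12`
(`forest_config(preset = "paper")`). The desk default is 2,000 trees: the
OOB NSE is essentially converged there (the suite checks that 2,000- vs
4,000-tree runs differ by < 0.01), while importance estimates keep getting
less variable up to much larger ensembles (also checked, at
500/2,000/8,000 trees), which is exactly why the reference analysis uses
20,000.

**Determinism.** All randomness flows from a Park–Miller Lehmer generator
whose update is computed in exactly representable double arithmetic, so the
identical stream can be replayed in plain R. The test suite contains a naive
explicit-loop reimplementation of the whole ensemble and requires
bit-for-bit equality of OOB predictions, including on data with heavy ties.
The implementation is single-threaded with one sequential stream (importance
uses a second stream derived from the seed, so growth is invariant to
whether importance is computed). An established library implementation
(`ranger`) is used in the tests as an independent statistical cross-check on
planted-signal data, never as the implementation.

**Importance.** Per tree, each feature used by that tree is permuted among
the tree's OOB subjects and the increase in OOB mean squared error recorded;
a feature a tree never splits on contributes an exact zero for that tree.
The default estimate divides the mean increase by its standard deviation
across trees (the convention of the MATLAB ensemble framework the reference
analysis used); `importance = "raw"` reports the mean increase itself. The
two differ by a positive per-feature scaling and agree on rankings of
clearly predictive features.

## Inference

* **NSE**: `1 − Σ(Y_m − Y_p)² / Σ(Y_m − Ȳ)²`, in (−∞, 1]; 1 is perfect,
  0 matches the observed mean, negative is worse than the mean. Constant
  observed vectors are an error (zero denominator).
* **Permutation test**: the outcome vector is shuffled, the forest refit
  with the same configuration (same number of trees; a desk preset is a
  clearly labelled scaled-down configuration), and the OOB NSE recorded;
  p is the fraction of null statistics **at or above** the observed one.
  The ≥ convention follows the "equal to or better" definition; with a
  continuous statistic the distinction from strict exceedance is
  measure-zero. p is reported as count/N (plug-in), which reproduces the
  worked examples 11/2000 = 0.0055, 13/2000 = 0.0065, 14/2000 = 0.007
  exactly; the conservative (count+1)/(N+1) variant is available. A zero
  count prints as "< 1/N".
* **Threshold**: alpha/n_tests (0.05/7 = 0.00714 for seven cognitive
  tests); 2,000 permutations give a p resolution of 1/2000 = 5e-4.
* **Peaks**: the importance profile is the per-bin mean across electrodes;
  a peak strictly exceeds both neighbours (one neighbour at the 1 and
  50 Hz edges — edge bins may be peaks) and lies more than one sample SD
  (denominator n−1, over the 50 profile values) above the profile mean.
* **Direction of effect**: at each peak, the top three channels by
  importance are followed up with univariate regressions of the outcome on
  that channel's residualized power, both variables z-scored, giving signed
  standardized betas in \[−1, 1\]. Covariates are not re-entered: power was
  already residualized upstream. Whether a second covariate adjustment
  belongs here is genuinely open; the package residualizes once, which
  keeps the univariate betas interpretable as partial effects given the
  stored covariate model.

## Clinical follow-ups

* **Welch's ANOVA** on residualized scores across diagnostic groups with
  more than 10 members (strict inequality — a group of exactly 10 is
  excluded), via the Welch–Satterthwaite heteroscedastic one-way test
  (fractional denominator df). An independent textbook-formula oracle backs
  the implementation in the tests.
* **Symptom correlations**: Pearson r with two-sided p per (outcome,
  dimension) pair over the five symptom dimensions
  (social/interpersonal, anxious, depressive, somatic, anomalous); raw
  p-values, no grid-level correction (deliberately, as in the reference
  analysis; noted in outputs).
* **Diagnosis control forests**: one *regression* forest per diagnosis on a
  one-vs-rest 0/1 indicator (graded predictions rather than a classifier),
  same configuration and permutation machinery. On cohorts whose labels are
  independent of the EEG — the synthetic default — none should beat chance.

## The synthetic cohort generator

No public data accompany the analysis this package implements, so the
generator is a first-class module with recoverable ground truth rather than
a test fixture:

* **Background**: per channel, independently shaped white noise with
  one-sided PSD `exp(background_level) · f^(−noise_exponent)` (flattened
  below 0.5 Hz to keep drift finite); defaults `background_level = log(20)`
  µV²/bin at 1 Hz, exponent 1 — a realistic eyes-closed 1/f backbone.
  Spatial correlation of the background is intentionally out of scope.
* **Oscillators**: band-pass-filtered Gaussian noise (4th-order Butterworth,
  shared across channels), scaled per channel so the added band power
  matches `exp(bg + w·L)` where `w` is the topography weight and `L` the
  subject's latent band log power, `L ~ N(mean_log_power,
  between_subject_sd²)`. The fast feature-level path writes
  `bg(f) + w·bump(f)·L` (+ covariate terms + N(0, measurement_sd) noise)
  directly, with a Gaussian spectral bump of width `bandwidth/2`. The two
  paths agree at the oscillator bins up to the log-of-sum vs sum-of-logs
  approximation, which the tests bound with a Monte-Carlo margin check;
  away from oscillator peaks the time-domain path also carries window
  leakage that the feature-level path does not model.
* **Outcomes**: `Σ slope·L + noise`; the slope's sign is the planted
  direction of effect. Error-count-like scores can be floored at 0.
  Additional pure-noise outcomes support null calibration.
* **Covariates**: age uniform on \[12.6, 64.6\] years (mean 38.6, SD 15.0),
  gender Bernoulli(0.384), optional per-bin age/gender slopes on power.
* **Diagnoses**: multinomial labels (defaults mirror a realistic seven-group
  transdiagnostic cohort with a dominant group), drawn independently of the
  EEG — so the expected diagnosis-prediction result is null by construction.
* **Symptom dimensions**: five independent standard normals, uncoupled by
  default.

What passing tests on this generator do *not* show about real data:
artifacts (blinks, muscle), volume conduction and spatially correlated
backgrounds, nonstationarity, and nonlinear or interaction-shaped
brain–behaviour couplings are all absent. The generator validates the
*machinery* (calibration, recovery, direction-of-effect signs), not the
neurophysiology.

## Presets, problem sizes, and why they look the way they do

The effect sizes of real EEG–cognition couplings are not published as
simulation-ready parameters, so the planted-signal preset is this package's
choice: `cohort_preset("acceptance")` uses n = 200 subjects, a 6 Hz
oscillator (bandwidth 2 Hz, between-subject SD 1) peaking at F4 with
coupling slope −1 and outcome noise SD 1.5 — a planted R² of ≈ 0.31
spread over a correlated block of features, which yields observed OOB NSE
around 0.1–0.2 and mirrors the qualitative pattern of a detectable but
modest association. The preset was sized once with a small pilot power
check and then frozen.

The validation suites run at deliberately chosen desk scales: null
calibration uses 100 nested runs of (n = 60, 200 features, 300 trees,
200 permutations); planted-signal recovery uses 12 seeded runs of the full
64-channel acceptance preset (500 trees, 200 permutations) requiring
success in at least 11; the null diagnosis suite uses 10 seeded runs of six
one-vs-rest models requiring at least 9 fully clean runs. These sizes keep
the whole suite's Monte-Carlo error small while remaining routinely
runnable; the underlying statistics (binomial acceptance regions, success
thresholds at the 90% level) are computed for the sizes actually run.

One caveat stated plainly: with 200 permutations, a null one-vs-rest model
crosses the 0.00714 threshold with probability 2/201 ≈ 1%, so six models ×
10 runs are expected to produce of order one spurious significance. The
"at least 9 clean runs of 10" requirement absorbs the expected case; it is
a property of the permutation resolution, not of the implementation.

## Known limitations

* The spectral module assumes cleaned, artifact-free input; no re-referencing,
  filtering, or artifact rejection is provided.
* Montage coordinates are a schematic top-view layout for plotting and
  distance-based topographies, not digitised positions; do not use them for
  source-space work.
* The permutation test refits the forest with the same tree count as the
  observed model; at the reference scale (20,000 trees × 2,000
  permutations) that is a compute-cluster job, and the desk presets exist
  precisely because of it.
* One-vs-rest diagnosis forests ignore comorbidity structure (multiple
  labels per subject are representable in the data model but not generated
  by default).
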