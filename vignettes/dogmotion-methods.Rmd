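---
title: "Behaviour recognition from canine-borne inertial sensors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behaviour recognition from canine-borne inertial sensors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A small inertial measurement unit strapped to a dog's back records
tri-axial acceleration (in g, body-fixed axes: x toward the head, y to the
right, z into the body) and tri-axial angular velocity (roll, pitch, yaw
rates in degrees/s) at 100 Hz. Human coders watching synchronized video tag
time intervals with one of seven non-overlapping behaviour categories —
three static postures (`lay`, `sit`, `stand`) and four gaits of increasing
intensity (`walk`, `trot`, `canter`, `gallop`). **dogmotion** turns these
two streams into a supervised behaviour classifier and, just as
importantly, into an evaluation framework that quantifies how well such a
classifier transfers across recording sessions, individuals and breeds.

The physical signal structure drives every design choice. During a static
posture the accelerometer measures essentially only gravity, so the three
acceleration channels encode the device attitude (a sitting dog pitches
the sensor nose-up; a lying dog rolls it); the gyroscope meanwhile sees
almost nothing. During locomotion both sensors carry near-periodic
oscillations whose fundamental frequency and amplitude grow with gait
intensity, and canter and gallop overlap substantially in both.

## Pipeline

1. **Ingestion** (`read_recording()`, `read_labels()`): recordings are
   seven-column CSV; annotations are SubRip (SRT) subtitle files, one
   behaviour name per cue. Intervals are half-open `[start, end)` in
   seconds on the recording clock; cue times are millisecond-precision and
   are aligned to the sample grid by flooring. Unknown cue texts are an
   error, never silently skipped — a user-supplied `category_map` handles
   non-canonical vocabulary.
2. **Margin trimming** (`apply_margin()`): one second is cut from both
   ends of every labelled interval and intervals shorter than two margins
   are dropped, guarding against imprecise annotation boundaries. The
   operation deliberately is *not* idempotent.
3. **Signal derivation** (`derive_signals()`): 14 per-sample scalars — the
   three acceleration components, |a|, the attitude tangent
   `r_xz = a_x/a_z`, the three angular rates, |w|, three angular
   accelerations (central differences, one-sided at the ends), the dot
   product `d = a·w` and the cosine alignment `c = d/(|a||w|)`. The
   tangent's denominator is clamped to ±0.05 g; during vigorous gaits
   `a_z` crosses zero and the raw ratio would otherwise explode. `c` is
   defined as 0 where a magnitude vanishes.
4. **Windowing** (`cut_windows()`): one-second windows (100 samples) that
   lie entirely inside a single labelled interval, advancing by 10 samples
   (0.1 s), i.e. roughly ten classifier nodes per labelled second. No
   window ever straddles a category boundary.
5. **Features** (`extract_features()`): nine statistics per signal — mean,
   standard deviation, skewness, excess kurtosis, minimum, maximum,
   mean-crossing count, dominant FFT frequency and dominant FFT magnitude
   — plus six low-order FFT harmonic magnitudes of |w| and a reduced
   (mean/min/max) set for `c`, giving exactly 126 features that partition
   into 45 accelerometer-only, 69 gyroscope-only and 12 mixed entries.
   The partition is asserted when the package loads.
6. **Normalization** (`fit_normalizer()`/`apply_normalizer()`): per-feature
   min-max scaling to [0, 1], learned from training data only; constant
   columns map to 0 and out-of-range values clip. Inside every
   cross-validation fold the normalizer is refitted on that fold's
   training split, so the held-out fold never leaks into the scaling.
7. **Classifier** (`train_classifier()`): a soft-margin SVM with Gaussian
   kernel `K(u,v) = exp(-gamma ||u-v||^2)`, one-vs-one multiclass voting
   (the libsvm default, via **e1071**), `C = 16`, `gamma = 0.001`. The
   defaults sit in the broad plateau of the `grid_scan()` surface — a
   coarse log2 lattice (`C` in 2^-5..2^15, `gamma` in 2^-15..2^3) scanned
   with stratified, seeded five-fold cross-validation — and deliberately
   favour generalization over per-measurement tuning.

## Evaluation framework

Validation always means *hold-out at the measurement level*: a
measurement (one dog, one session) is never on both sides of a
training/validation pair, and `validate_pair()` raises before any
computation if it is. Six comparison schemes probe transfer
(`run_scheme()`): within-dog (train one session, validate the dog's other
session), intra-breed and inter-breed single-measurement pairs, and three
multiple-training schemes that pool 1+1, 3+3 or 5+5 dogs from the two
breeds and validate on dogs absent from training. Dogs enter through
their *more comprehensive* measurement — the session whose scarcest
category has more windows (`comprehensiveness()`, `rank_measurements()`;
ties break by total window count, then dog id).

Errors are graded by an activity-level taxonomy: levels 0 (static
postures), 1 (walk), 2 (trot), 3 (canter, gallop). A prediction is a
*perfect match* (correct category), an *imperfect match* (wrong category,
same level) or a *mismatch* at ΔA = 1, 2 or 3; the five percentages always
sum to 100. Recognition matrices cross-tabulate true against predicted
categories, row-normalized to 100%; rows with no true windows are
undefined (`NA`), not zero, and per-calculation matrices are averaged
entrywise across a scheme's calculations.

`f_scores()` ranks single features by the ratio of between-category to
within-category variance. The cited two-class F-score has no unique
multiclass form; we use the between/within sum over all seven categories,
which reduces to the two-class definition for two categories — an explicit
design choice, frozen and tested against a brute-force evaluation.
`subset_cv()` compares stratified five-fold CV accuracy under the three
column masks (126 / 45 / 69 features). `intercoder_agreement()` evaluates
two coders' tracks on a shared 0.1-s node grid, reporting each coder's
exclusive fraction and a row-normalized 7×7 agreement matrix on common
nodes.

## The synthetic study generator

No public recording accompanies the method, so the package ships a seeded
simulator (`make_population()`, `generate_session()`, `generate_study()`)
that reproduces the *statistical structure* the pipeline relies on, not
canine biomechanics:

* **Static postures** are a rotated 1 g gravity vector (stand pitch 5°,
  sit pitch 35°, lay roll 10°) plus Gaussian channel noise (0.03 g,
  3 °/s) and a small panting oscillation (per-dog frequency near 5.3 Hz)
  that is *identical across the three postures* — so gyroscope features
  carry no posture information by construction, which is exactly why
  accelerometer-only models beat gyroscope-only models on the simulated
  data.
* **Gaits** superimpose a three-harmonic series (amplitude halving per
  harmonic, random phases per segment) of a stride frequency on the
  gravity baseline: walk 1.8 Hz, trot 3.0 Hz, canter 3.6 Hz, gallop
  4.0 Hz, with per-axis amplitudes growing with gait intensity and noise
  of 0.08 g / 8 °/s. Canter and gallop are deliberately close so their
  per-individual distributions overlap and the classifier's dominant
  confusion is that pair.
* **Individuals and breeds**: each dog draws lognormal multiplicative
  factors for frequency and amplitude (sigma `sigma_ind`, default 0.1),
  an attitude jitter (SD `30·sigma_ind` degrees) and a panting frequency;
  breed offsets (Malinois ×1.06 frequency, ×1.10 amplitude, +2° pitch)
  separate the two populations. Setting `sigma_ind = 0` collapses each
  breed to identical dogs — the control under which the within-dog versus
  between-dog gap must vanish, and does.
* **Sessions**: a dog's two measurements share its profile but draw
  independent noise and a small lognormal session factor (sigma 0.03 on
  frequency and amplitude), modelling day-to-day variation — the reason
  within-dog validation is excellent but not trivially perfect.
* **Scripts**: sessions follow a predetermined behaviour series with 2-s
  unlabelled transition gaps (emulating interrupted annotation); the
  default script runs each category for 80 s (≈10 min total).
  `simulate_second_coder()` derives a second annotation by jittering
  boundaries (SD 0.3 s) and occasionally relabelling within an activity
  level (3%), emulating independent human coding.

What the simulator does *not* emulate: genuine gait kinematics and
transients, gravity/body-acceleration coupling during manoeuvres,
temperature drift, sensor mis-attachment, or behaviours outside the
seven-category ethogram. Green tests therefore demonstrate that the
pipeline's machinery — features, normalization discipline, hold-out
schemes, error taxonomy — behaves correctly and reproduces the expected
*orderings* (within-dog > between-dog, more training dogs ≥ fewer,
accelerometer > gyroscope, canter↔gallop dominant confusion); they are not
evidence about accuracy on real dogs.

## Numerical conventions

* Skewness `m3/m2^1.5` and excess kurtosis `m4/m2² − 3` from central
  moments with the 1/n convention; both defined as 0 for zero-variance
  windows to avoid NaN propagation. Standard deviation uses n−1.
* Mean-crossing count: sign changes of the mean-centred window after
  discarding exact zeros.
* FFT features use the unwindowed (rectangular) transform of the
  100-sample window; only bins 1..50 (DC excluded) compete for the
  dominant bin, ties resolved toward the lower frequency; magnitudes are
  amplitude-scaled (2|X|/n) so a pure sinusoid of amplitude A scores A.
  The six |w| harmonic features are the magnitudes of bins 1–6 (1–6 Hz at
  the default rate).
* Stratified CV folds deal a seeded per-category shuffle round-robin;
  every stochastic entry point requires an explicit seed and restores the
  caller's RNG state.

## Problem sizes

Exercising the full framework end-to-end is compute-heavy (dozens of SVM
fits per scheme), so the packaged experiments run the simulator at desk
scale, chosen once: the test-suite and acceptance-script studies use the
full 12+12-dog, two-session design but 8–10 s per behaviour (≈500 windows
per measurement), 10 calculations per scheme (5 for the multiple-training
schemes inside the 10-replicate ordering experiment), and controls on
4-dog-per-breed populations. The qualitative orderings above are stable at
this scale across replicate seeds; absolute percentages naturally differ
from a field study's.

## Known limitations

* The 126-feature manifest realizes the documented counts (45/69/12) with
  a uniform nine-statistic template per signal; a differently composed
  manifest with the same counts could be substituted via
  `feature_manifest()`-compatible tables without touching the pipeline.
* The multiclass F-score variant and the pairing of dogs within
  comparison schemes (seeded random without replacement) are package
  design choices among several defensible options.
* The simulator's category templates are stationary within a segment;
  real behaviour is non-stationary at every scale.
* No attitude estimation is performed; features see raw body-frame
  signals only.
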