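---
title: "Methods: wearable-sensor surgical skill assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable-sensor surgical skill assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `surgskill`, and what the synthetic cohort does and
does not establish about real data.

## The measurement model

Each recording unit is one (subject, skill, task, trial, muscle, side)
combination carrying a 2000 Hz surface-EMG channel, three 100 Hz
accelerometer axes, a resting-baseline EMG segment and an MVC reference
amplitude.  Skill is treated as a three-level label (novice,
intermediate, expert).  Two families of features are extracted:

* **Muscular workload (linear EMG features).**  The EMG envelope is the
  signal after detrending, 20–500 Hz band-pass, 60 Hz notch, 6-sample
  windowed-RMS rectification and 4th-order 5 Hz low-pass, divided by the
  MVC amplitude.  Cumulative muscular workload is the trapezoidal time
  integral of this envelope; average work per second divides it by the
  trial duration; activation time spans the first to the last envelope
  sample above the baseline threshold (baseline mean + 5 SD, sample SD
  with the n−1 denominator).  RMS, range and dominant frequency are
  computed on the filtered signal before rectification, since
  rectification halves the spectral content they are meant to describe.
* **Movement variability (nonlinear accelerometer features).**  All are
  computed from the resultant acceleration.  Approximate and sample
  entropy quantify template regularity; multiscale entropy repeats
  sample entropy on coarse-grained copies; correlation dimension
  measures attractor fractal dimension; Rosenstein and Wolf estimators
  measure the largest Lyapunov exponent; the generalized Hurst exponent
  measures long-range correlation.

## Parameter choices for the nonlinear features

The literature behind these statistics leaves the embedding and
tolerance parameters to the analyst; the defaults here are the common
physiological-time-series conventions, all exposed in
`nonlinear_params()`:

* template length `m = 2` for the entropies, embedding dimension
  `m = 3` for correlation dimension and Lyapunov estimation;
* embedding lag `tau` from the first minimum of the average mutual
  information (16-bin histogram), falling back to the first
  non-positive autocorrelation lag;
* entropy tolerance `r = 0.2 * SD` of the series.  Multiscale entropy
  keeps `r` fixed from the *original* series' SD across scales (the
  standard convention, so that coarse-graining-induced variance loss
  registers as falling entropy); per-scale tolerances are available by
  flag;
* coarse-graining scales 1–10;
* Chebyshev distance for entropy templates (their defining convention),
  Euclidean distance for correlation sums and Lyapunov neighbours;
* the correlation-sum Heaviside step is strict (`distance < r`), so
  ties at exactly `r` do not count;
* the correlation-dimension slope is fitted on a 12-point geometric
  radius grid spanning the 1st–10th percentiles of the pairwise
  distance distribution.  Larger radii are deliberately excluded: on a
  bounded attractor the correlation sum saturates and edge effects
  flatten the log–log slope (on 2000 points uniform in a square the
  slope over the 5th–50th percentile range reads ≈ 1.7 instead of 2);
* Rosenstein: nearest neighbours must be separated in time by more than
  the mean period (reciprocal of the power-weighted mean frequency);
  the exponent is a degree-1 least-squares fit to the mean
  log-divergence curve over a configurable expansion range, short- and
  long-term variants fit over `[1, P/2]` and `[P/2, 2P]` samples
  (P = mean period), the usual movement-variability convention.  The
  very first divergence steps sit below the linear region (the
  neighbour pairs start at the noise floor of the nearest-neighbour
  distance), so validation fits start a few steps in, exactly as the
  method's authors prescribe choosing the linear region;
* Wolf: evolution interval of 5 samples and a neighbour search radius
  of 0.2 × attractor extent.  Shorter evolutions with tighter radii
  re-select a compressed nearest neighbour too often and bias the
  exponent upward;
* generalized Hurst: structure-function slope over lags 1–19 after
  integrating the (mean-removed) series, so iid noise scores H = 0.5
  and a smooth trend scores 1.  Feeding an already-integrated walk
  therefore saturates near 1 — a documented property of this
  convention, not an error;
* series longer than 1500 samples are decimated before the O(N²)
  kernels; at the 100 Hz accelerometer rate this caps the cost of a
  recording at roughly a 15 s window without touching the EMG path.

Degenerate inputs (constant series, no matching templates, empty
scaling regions) yield flagged `NA`s — never silent zeros or
infinities — and flagged values propagate as missing into the feature
table, where imputation is explicit (train-median, fitted on the
training partition only).

## EMG preprocessing conventions

Filters are Butterworth and applied forward–backward, so the envelope
is zero-phase and activation onsets are not delayed; tone tests in the
suite check the pass/stop contracts at steady state, away from the
filter's edge transients.  At a 2000 Hz sampling rate the 500 Hz upper
band edge is exactly half the Nyquist frequency and usable as-is; for
rates below 1100 Hz the edge is clamped to 0.45 × fs with a warning.
The windowed RMS is centred with edge truncation.  Detrending removes a
least-squares line — strictly more general than mean removal and
identical to it for trendless signals.  The dominant-frequency argmax
excludes the DC bin (detrending leaves it near zero anyway) and breaks
ties toward the lower frequency.

Two readings of the feature definitions were genuinely open and are
resolved as follows, with flags to switch: the AWS denominator is the
whole-trial duration (task completion time), not the activation time;
activation time is first-onset-to-last-cessation, not the sum of
above-threshold episodes.

## The synthetic cohort

`generate_cohort()` emulates the statistical structure the analysis
assumes, not surgical biomechanics:

* **EMG**: a Gaussian carrier band-limited to 20–450 Hz (so
  preprocessing does not destroy it) multiplied by a burst-train
  envelope; bursts are Poisson in time with Gaussian shapes.  Skill
  templates differ in burst rate, duration, amplitude and task
  duration: novices co-contract more densely and longer.  Defaults:
  novice/intermediate/expert burst rates 1.2/0.9/0.6 per second, burst
  durations 1.0/0.7/0.5 s, amplitudes 0.65/0.5/0.38 of MVC, and task
  durations 32/24/18 s for pegboard and robotic suturing.  Knot tying
  uses a common duration for all groups, reflecting that this task
  takes all groups similar time.
* **Accelerometer**: each axis is a weighted mix of a sinusoid
  (1.5 Hz, the gross arm-movement band), a chaotic-flow trajectory (a
  canonical three-variable flow with known positive largest exponent,
  integrated with a fixed-step 4th-order Runge–Kutta scheme, transient
  discarded) and white noise, each component normalized to unit peak
  before mixing, so the per-axis peak is bounded by the amplitude
  parameter.  Novice/intermediate/expert noise weights 0.45/0.20/0.05
  make the novice group the most entropic, matching the direction of
  the reported group differences in multiscale entropy.
* **MVC** is 2 × the subject's maximum task-envelope amplitude per
  muscle and side — no MVC trial is modelled, so normalized envelope
  *amplitudes* are comparable across groups by construction and the
  workload differences are carried by activation density and duration.
* **Cohort sizes** default to 10/11/5 subjects per group.  The study
  design this emulates reports slightly different counts in different
  places; the generator takes the methods-section counts and leaves the
  sizes user-settable rather than pretending to resolve the
  discrepancy.
* Between-subject variation is log-normal jitter (SD 0.08) on the
  activation parameters and mixture weights.  `muscle_effects` blends
  any muscle's profiles toward the skill-neutral (intermediate)
  template, which is how the tests plant signal in a single muscle.

What passing tests show: the pipeline recovers planted group structure,
ranks a genuinely informative muscle first, collapses to chance under
label permutation, and every estimator agrees with independent oracles
on constructions with known answers.  What they do not show: that real
surgical EMG has burst-Poisson structure, that real movement complexity
is a three-component mixture, or that the real-data accuracies of any
particular study are reproducible — those depend on recordings this
package does not ship.

## Classification protocol

Features are median-imputed and standardized with train-fitted
statistics, then fed to a 100-tree random forest, Gaussian naive Bayes
and an RBF-kernel SVM.  The split is stratified 70/30 and
subject-grouped by default: all trials of a subject fall on one side,
preventing identity leakage across partitions (row-level splitting is
available for protocol-fidelity runs, since published analyses of this
kind often split rows).  Reported metrics come from the one-vs-rest
reading of the 3×3 confusion matrix; precision uses the standard
TP/(TP+FP) denominator, and macro averages are reported alongside
per-class values.  ROC curves sweep each class's score with trapezoidal
AUC.  Muscle combinations concatenate the member muscles' feature
columns per (subject, task, trial); pooling left/right rows instead of
concatenating per-side features is exposed through the table builder.

## Determinism and problem sizes

Every random draw derives from one global seed through a documented
integer-mixing function (`derive_seed`), per stage and per generated
unit, so isolated stage re-runs agree with full-pipeline runs and
artifact checksums reproduce exactly; numeric artifacts are serialized
with 17 significant digits so text round-trips are bit-exact.  The test
suite and the acceptance script run reduced problem sizes — single
task, single side, two to three trials, duration scale 0.5, i.e. a few
hundred recordings of 10–20 s — chosen so the full validation remains a
desk-scale computation while every recording still yields at least a
thousand accelerometer samples for the nonlinear estimators.

## Known limitations

* The Wolf estimator omits the angular replacement constraint of the
  full trajectory-tracking algorithm; with the default evolution and
  radius settings it recovers map exponents within the validated
  tolerance, but it is the weaker of the two Lyapunov estimators here.
* Entropy and correlation statistics are O(N²); the decimation cap
  trades a small amount of estimator variance for bounded runtime.
* The generator's task durations are drawn independently per muscle
  site rather than shared across a trial's simultaneous channels — a
  simplification that does not affect per-muscle analyses but would
  matter for cross-muscle timing features, which the package does not
  compute.
* No artifact removal (ECG contamination, motion spikes) is modelled or
  implemented; inputs are assumed to be clean recordings.
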