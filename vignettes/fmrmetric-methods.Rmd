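---
title: "Comparing fMR-metric and psychometric functions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing fMR-metric and psychometric functions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

When an observer judges the depth sign (near vs. far) of a disparity-defined
plane while fMRI is acquired, two curves can be measured simultaneously: the
*psychometric function* — proportion correct as a function of signal strength
— and the *fMR-metric function* — the accuracy with which a classifier can
decode the depth sign from region-of-interest (ROI) voxel patterns, as a
function of the same signal strength. A cortical area whose decoding accuracy
rises and saturates the way behavior does is a candidate locus for the
perceptual read-out; an area that decodes only the clean stimulus and
collapses as soon as noise is introduced is not. `fmrmetric` implements that
comparison end to end, with a synthetic generator standing in for scanner
data so that every stage is testable.

## The design: one-back balanced event-related runs

Runs contain `n_conditions × reps + 1` contiguous 3 s trials. For the
standard signal-in-noise configuration there are 11 conditions (5 signal
levels × near/far, plus fixation) × 11 repetitions = 121 analyzed trials,
preceded by one *dummy* trial so that even the first analyzed trial has a
balanced one-trial-back history. `generate_balanced_sequence()` draws a
random Eulerian circuit on the complete digraph over conditions (self-loops
included) via Hierholzer's algorithm; a circuit traverses every ordered pair
of conditions exactly `reps / n_conditions` times, so the one-back transition
matrix is exactly uniform — with 11 × 11 each of the 121 ordered pairs occurs
exactly once. Because the circuit closes, the dummy's label necessarily
equals the last trial's label; that is this package's rule for choosing the
dummy (the balancing argument fixes everything else, but not that choice —
any label admitting a circuit would do).

Each trial is 300 ms of stimulus, a 1.2 s (75% of trials) or 1.4 s (25%)
delay, then a response cue removed 300 ms before the next onset. On trial
counts not divisible by 4, the 3:1 delay split uses nearest-integer counts
with ties resolved toward 1.2 s. Runs begin and end with 9 s of fixation;
122 trials thus give a 384 s run — 256 volumes at TR = 1.5 s.

## The psychometric model

Performance is modeled as a cumulative Gaussian with guess and lapse rates,

$$\psi(s) = \gamma + (1 - \gamma - \lambda)\,\Phi\!\left(\frac{s-\mu}{\sigma}\right),$$

where `mu` is the location (stimulus units: % signal or arcsec), `sigma` the
slope scale (> 0, same units), `gamma` the lower asymptote (fixed at 0.5 for
the two-alternative depth judgment) and `lambda` the upper-asymptote deficit,
free within [0, 0.06] — wide enough to absorb real lapsing and the mild
saturation deficit of plausible observers, narrow enough that the threshold
stays identified from 5 levels. Fitting maximizes the binomial likelihood of
per-level correct counts with bounded quasi-Newton (L-BFGS-B) from a
deterministic 5 × 5 start grid over (`mu`, `sigma`); the best likelihood
wins, ties to the first start. The 75% threshold is obtained analytically
through the inverse normal. All-correct or all-chance data return a fit
flagged `degenerate` with parameters at the box boundary.

**Fitting axis.** The signal-in-noise task is fitted on a linear axis (its
levels include 0% signal). The feature-difference task is fitted on a
`log10` axis by default: its levels (6–240 arcsec) are spaced
multiplicatively, and simulation shows that linear-axis fitting of a
realistic observer in this design carries a consistent ≈ +2 arcsec threshold
bias that log-axis fitting removes (the package's parameter-recovery test
quantifies this). A linear option remains available.

## The synthetic ROI generator

`simulate_roi_run()` builds `baseline + drift + trial increments + noise`:

* each voxel has a *selectivity* $s_v \in [-1, 1]$ (uniform by default, a
  bimodal option exists), drawn **once per ROI** and held fixed across runs;
* a non-fixation trial at level $L$ with depth sign $d \in \{+1,-1\}$ adds
  $A \, g(L) \, d \, s_v$ to `response_width = 2` volumes starting
  `delay_volumes = 3` volumes after `onset/TR` — a *delayed boxcar*, not an
  HRF convolution, because the analysis only shifts and averages volumes and
  a boxcar keeps every index-arithmetic oracle exact;
* the coupling $g$ maps level to [0, 1] with $g(0)=0$; the default is
  `level/100`, and `coupling_from_psychometric()` builds
  $g \propto \psi - \psi(0)$ for the regime where decoding should track
  behavior;
* drift is a linear slope plus a slow sinusoid (default 1.5 cycles/run,
  inside the 3 cycles/run high-pass band); noise is i.i.d. Gaussian.

Behavioral responses are per-trial Bernoulli draws with $p=\psi(L)$. A master
seed expands deterministically (`derive_seed()`) into per-run, per-draw
streams, so any component can be regenerated alone.

**What the generator does not emulate:** realistic HRF shapes and their
overlap between 3 s trials, spatial and temporal noise autocorrelation,
physiological noise spectra, motion, multi-ROI correlated noise, or any
dependence between behavioral responses and the voxel noise (no
choice-probability structure). A green end-to-end test therefore establishes
that the *pipeline* is correct and well calibrated under its own
assumptions; it says nothing about scanner realism.

**Amplitude regime.** Two regimes are used deliberately in the tests. At
amplitude 3 × noise SD the patterns are nearly separable — right for
separability and index-arithmetic checks, but decoding then saturates by the
lowest nonzero level and the permutation null widens (a shuffled labeling
that happens to overlap the true one classifies separable clusters well).
The demonstration "coupled" ROI instead uses amplitude 0.12 × noise SD: a
per-voxel effect far below single-voxel detectability that becomes reliable
only through 300-voxel patterns, the regime event-related MVPA actually
occupies, where top-level accuracy lands near 0.9 and intermediate levels
grade with $g$.

**A degenerate corner.** With `noise_sd = 0` every voxel is an exact
multiple of one common time course. Then (i) the stimulus-vs-fixation t
ranking retains only voxels of one selectivity sign, and (ii) after per-run
z-scoring those voxels are identical, so mean-pattern subtraction
annihilates the signal. This cannot arise in noisy data; noiseless
separability is therefore asserted on the shift → extract → average →
normalize path with sign-mixed selectivity.

## Preprocessing

Fixed order, asserted by a canary test: high-pass filter + linear detrend →
hemodynamic shift → voxel ranking → trial-window extraction → trial
averaging → z-score → mean-pattern subtraction.

* **High-pass / detrend** (`highpass_detrend`): per voxel, least-squares
  removal of intercept + slope and of sine/cosine pairs at 1–3 cycles/run.
* **Shift** (`shift_timeseries`): output volume *t* = input volume *t* + 3
  (4.5 s at TR 1.5 s); trailing volumes dropped, onsets untouched.
* **Ranking** (`rank_voxels`): pooled two-sample t (pooled-variance form) of
  stimulus-trial vs fixation-trial volumes across all runs; retain t > 0,
  descending t, top 300 (or all available), ties broken by ascending index.
  The contrast never sees the near/far labels.
* **Extraction** (`extract_trial_patterns`): each trial's pattern is the mean
  of the 2 volumes starting at `round(onset/TR)` after the shift (0-based,
  half-open); at 3 s trials and TR 1.5 s that is exactly the trial's slot.
  This window is a package convention — the length of the averaged window is
  not dictated by the analysis it reimplements.
* **Averaging** (`average_trials`): within run × condition, consecutive
  groups of (4, 4, 3) trials in presentation order give 3 patterns per
  condition per run.
* **Normalization** (`normalize_patterns`): per run, per voxel z-score
  across that run's patterns (zero-variance voxels zeroed and flagged), then
  per pattern subtraction of the cross-voxel mean. Z-scoring is applied at
  the averaged-pattern stage by default; a `zscore_stage = "timeseries"`
  switch z-scores the raw shifted series instead — the two differ only by
  grouping weights, and the switch keeps the ambiguity explicit.

## Decoding

A linear soft-margin SVM is trained on near/far patterns of the *highest*
signal level (the most reliable training data) from all runs but one and
tested on every level of the held-out run; each run is held out once
(leave-one-run-out). With 9 runs this gives 48 training and 6 test patterns
per level per fold; accuracy per level is the mean over folds, and chance
for the balanced binary problem is 0.5.

The cost parameter is data-dependent:
$C = n_\text{folds} / \sum_i \lVert x_i \rVert^2$ by default, computed per
fold from its own training patterns. The defining phrase ("inverse of the
summed squared training data, divided by the number of cross-validations")
admits a second reading, $C = 1/(\sum_i \lVert x_i\rVert^2 \, n_\text{folds})$,
available via `divide = TRUE`; the rule used is recorded in output metadata.

The SVM dual QP is solved with `quadprog` (tiny ridge on the Gram matrix for
strict positive-definiteness; no randomized initialization, so results are
deterministic). A score of exactly 0 resolves to the lexicographically first
class label. Small instances are verified against a brute-force primal grid
oracle in the tests.

## Permutation nulls and the chance band

`permutation_null()` repeats the full leave-one-run-out procedure with the
*training* labels permuted within each fold's training set (test labels
intact — a both-shuffled variant exists behind `shuffle_test`) and records
the mean accuracy at the training level; 999 iterations for the standard
criterion. Centiles use the nearest-rank (ceiling) rule. Significance is the
one-tailed upper 99.5th centile (0.5% per ROI, i.e. 5% Bonferroni-style
across a dozen ROIs); the *chance band* is the 32nd–68th centile interval
(≈ ±1 SE for a roughly normal null) and anchors the fMR-metric lower
asymptote. "Resampling" here is permutation without replacement — that is
the operation the procedure actually requires, whatever it is called.

## fMR-metric fits

* **Free fit** (`fit_fmrmetric`): least-squares cumulative Gaussian with the
  lower asymptote constrained to the chance band and the upper free in
  (lower, 1]; multistart L-BFGS-B, tie to first start. Flat-at-chance data
  give a flagged degenerate fit.
* **Scaled behavioral fit** (`scaled_behavioral_fit`): `mu` and `sigma` are
  carried over from the behavioral fit unchanged; the lower asymptote is
  *fixed* near chance (default: the null median clamped into the band — the
  constraint "within the band" plus "one free parameter" forces a fixed
  lower, and the null's center is the natural choice); the upper asymptote
  is the single free parameter with a closed-form least-squares solution,
  clamped to (lower, 1] and flagged if driven to the floor. Least squares is
  unweighted. The scaled model is nested in the free fit, so its residual
  can never be smaller (a property test enforces this up to solver slack).
* **Goodness of fit** (`goodness_of_fit`): Pearson r between observed
  accuracies and scaled predictions with a two-sided p from the t transform
  on n − 2 df; R² is reported alongside. With 5 levels and one free
  parameter these p-values are fragile — `warning_low_n` flags n < 5, and no
  inferential weight should rest on them alone.
* **Saturation control** (`saturation_regression`): OLS slope of accuracy on
  stimulus magnitude with a t-based 95% CI; a CI covering zero supports the
  verdict that accuracy has saturated. Exact fits (zero residual) are
  flagged since the CI degenerates.

## Numerical conventions

Solver tolerance for the SVM dual is effectively machine precision plus a
`1e-10`-scaled ridge; bound-constrained fits clamp L-BFGS-B output to the
box (the optimizer can overshoot by machine epsilon); fixed parameters
(lapse, band of zero width) are removed from the optimization rather than
bounded to a point; percentile ties are resolved by the ceiling rule;
zero-variance voxels z-score to 0 with a flag; voxel-ranking ties break by
ascending index. All randomness flows from one integer seed through
`derive_seed()` (an LCG mix kept below 2^31).

## Known limitations

Single synthetic "subject" per pipeline run (no between-subject averaging,
which is how the original comparison gains its stability); no GLM beta
estimation, searchlights, or nonlinear kernels; NIfTI ingestion is an
extension point, not implemented; p-values on 5-point correlations are
reported but fragile; the permutation count bounds the attainable
significance level at 1/(n_perm + 1).
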