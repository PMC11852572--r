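---
title: "Methods: signal models, labeling rule and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal models, labeling rule and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldperf)
```

`coldperf` detects deterioration of cognitive task performance during cold
exposure from two wearable channels: skin conductance (electrodermal
activity, EDA) and the electrocardiogram. This vignette documents the
models and the decisions behind them — what is computed, with which
parameters and defaults, which choices were genuinely open, and what the
synthetic-data tests do and do not demonstrate about real recordings.

## 1. Phasic/tonic EDA decomposition

Skin conductance mixes a slowly drifting tonic level with discrete,
stimulus-locked skin conductance responses (SCRs). We model a recording
`y` (µS, sampled at `fs`, nominally 4 Hz) as

$$y = K p + B \ell + C d + \varepsilon, \qquad p \ge 0,$$

where `p` is a sparse non-negative sudomotor driver at the sampling grid,
`K` convolves it with a Bateman bi-exponential response
$h(t) \propto e^{-t/\tau_0} - e^{-t/\tau_1}$ normalized to unit peak
(decay $\tau_0 = 2.0$ s, rise $\tau_1 = 0.7$ s — the canonical constants
of the convex-decomposition literature), `B` is a cubic B-spline basis
with knots every 10 s carrying the tonic level, and `C` holds an offset
and a linear drift. The estimate solves the convex program

$$\min_{p \ge 0,\,\ell,\,d}\;
  \tfrac12\lVert y - Kp - B\ell - Cd\rVert^2
  + \alpha\,\mathbf{1}^\top p
  + \tfrac{\gamma}{2}\lVert \ell \rVert^2$$

with $\alpha = 8\times10^{-4}$ and $\gamma = 10^{-2}$. The phasic
component (PhEDA) is $Kp$, the tonic component (TonEDA) is $B\ell + Cd$.

**Solver.** The tonic block is a ridge least-squares problem with a
closed-form solution, so it is eliminated analytically; the remaining
non-negative lasso in `p` is solved by accelerated proximal gradient
descent (FISTA) with FFT convolutions for `K` and `Kᵀ`, a power-iteration
Lipschitz estimate (deterministic start vector — the decomposition never
touches the RNG), a convergence test on the relative objective change
(`tol = 1e-7`, checked every 25 iterations, `max_iter = 1000`), and a
warning if the budget is exhausted. Recordings longer than five minutes
are processed in 5-minute chunks with 60 s overlap, keeping each chunk's
central region; the tonic spline is refit per chunk, which can leave small
seams at chunk joins — irrelevant at the one-minute feature scale but
worth knowing for whole-recording plots. On noiseless synthetic signals
the recovered phasic correlates with the generating kernel sum at > 0.999
and the residual carries < 5% of the centered signal power.

**Degenerate inputs.** A constant recording yields an exactly zero driver
(any activation costs $\alpha$ and explains nothing) and a constant
tonic. The program is strictly convex in the tonic block and convex in
`p`; the $\ell_1$ term makes the map from signal to components positively
homogeneous only up to the (small) sparsity penalty, which the tests
check at a 5% tolerance.

## 2. Time-varying sympathetic index (TVSymp)

TVSymp is the instantaneous amplitude of the EDA signal reconstructed in
the 0.08–0.24 Hz band, where sympathetically mediated EDA oscillations
concentrate. The window is resampled to 2 Hz, normalized to zero mean and
unit variance — TVSymp is therefore unitless, and invariant to the
input's offset and scale — and decomposed by variable-frequency complex
demodulation (VFCDM): a bank of complex demodulators at carriers
$f_k = (2k-1)F_w$, $F_w = 0.03$ Hz, $k = 1..8$, each low-passed to
half-bandwidth $F_w$; the components with carriers inside the band
(0.09, 0.15, 0.21 Hz) are refined by a second demodulation along each
component's smoothed instantaneous frequency and summed; the Hilbert
envelope (analytic-signal magnitude, computed by FFT) of the sum is the
index.

Two implementation decisions matter and were genuinely open:

* **Low-pass design.** A short time-domain FIR at 2 Hz has a transition
  band wider than the component spacing, so neighbouring components
  overlap and a single in-band tone would be reconstructed with gain well
  above one. We instead use a zero-phase FFT low-pass whose raised-cosine
  transition is symmetric about $F_w$ (gain 1 below $0.4F_w$, 0.5 at
  $F_w$, 0 above $1.6F_w$): the bank then tiles the spectrum with unit
  total gain. A unit-variance tone anywhere near a carrier is returned
  with envelope $\sqrt2$ to within a fraction of a percent, and a 0.5 Hz
  tone is rejected below 0.1.
* **What the second stage demodulates.** Refining against the *raw*
  signal lets every component's instantaneous-frequency estimate lock
  onto a dominant oscillation — even one that leaked in at −40 dB — and
  the oscillation is then counted once per component. The refinement is
  therefore applied to each first-stage component, with its carrier
  clamped to the component's own band, so a component can never exceed
  its first-stage energy share.

## 3. SCR counting, windows, HRV features

**Windows.** All features summarize a one-minute window centered on the
task midpoint, in the half-open convention `[mid − 30 s, mid + 30 s)` at
native rate — exactly 240 samples at 4 Hz. The decomposition and TVSymp
are computed on a 120 s context window (shifted inward at recording
edges) and the central minute is extracted, so filter and solver edge
effects fall outside the scored region.

**NSSCR.** An SCR is a local maximum of the phasic component whose
onset-to-peak amplitude (peak minus preceding local minimum) exceeds the
threshold, with a 1 s minimum inter-peak separation (larger peak wins).
Two thresholds are counted, 0.05 µS and the more permissive 0.01 µS —
cold-attenuated skin keeps many responses small. Counts are monotone
non-increasing in the threshold by construction.

**R peaks.** 5–25 Hz zero-phase Butterworth band-pass, squared
derivative, 150 ms moving-window integration, an adaptive threshold at
20% of the 99th percentile, 250 ms refractory period, and refinement to
the local extremum of |band-passed signal| — which makes the detector
invariant to polarity and amplitude scaling. On synthetic ECG it recovers
≥ 99% of beats within one sample at 256 Hz.

**R-R cleaning.** Intervals outside [300, 1500] ms are invalid; an
interval differing from the previous *accepted* interval by more than 20%
(Malik's rule) is invalid; invalid intervals are replaced by linear
interpolation between the nearest valid neighbours, and the operation is
idempotent. A window more than half invalid is refused rather than
repaired.

**HRV features.** From cleaned windowed intervals: HR = 60000/mean(RR);
RMSSD = RMS of successive differences; HF = absolute power in
0.15–0.4 Hz, estimated by cubic-spline resampling of the interval series
to 4 Hz, mean removal, and a single Hann-windowed periodogram over the
minute, scaled so a modulation of amplitude $a$ ms integrates to
$a^2/2$ ms². The estimator choices (resampling rate, detrending, single
window) were open; the sinusoid oracle pins the calibration. An interval
straddling the window edge belongs to the window that contains its
terminating beat.

## 4. The deterioration label

Per subject and task, the five normal-condition session reaction times
form the baseline; the threshold is the **2nd slowest** of them, and a
cold-condition session strictly slower than the threshold is labeled
*deteriorated*. Ties (a session exactly at the threshold) stay normal.
SRT is excluded from labeling and evaluation (it shows no cold effect)
but is fully supported as data. The per-session summary statistic is the
mean reaction time of correct trials; the choice (mean vs median) was
open and is isolated in one place.

One property deserves emphasis because it is easy to get wrong. The
threshold is the empirical 80th percentile of five values, but the
probability that a *fresh* exchangeable draw exceeds the 2nd largest of
five i.i.d. values is not 0.2: the new value must rank 1st or 2nd among
all six exchangeable values, so the probability is $2/6 = 1/3$. The 0.2
figure applies to the population 80th percentile, i.e. in the limit of an
infinite baseline. The package's Monte-Carlo tests assert the
finite-sample value; with five baseline sessions, an i.i.d.-behaving
subject is expected to have about a third of cold sessions flagged, not a
fifth. Any analysis that treats the flagged fraction as a calibrated
false-positive rate should keep this in mind.

## 5. Comparison statistics

Features are compared between normal-performance and deteriorated
segments (the segment, not the subject, is the statistical unit) with a
two-sided pooled-variance Student's t-test, and effect sizes are pooled-SD
Cohen's d,

$$d = \frac{\bar x_2 - \bar x_1}{s_p},\qquad
  s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2},$$

with group 1 = normal, group 2 = deteriorated, so positive d means the
feature is elevated under deterioration. The 95% CI uses the
large-sample standard error
$\sqrt{(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2-2))}$ with normal quantiles —
an approximation adequate at these group sizes; an exact noncentral-t CI
was not required by any downstream consumer. The unpaired test is used
because the two groups have unequal sizes by construction.

## 6. Evaluation protocol

Classification of normal vs deteriorated segments runs under
leave-one-subject-out (LOSO) cross-validation; subject independence is
the point, since per-subject baselines already absorb individual means.
Per fold:

1. **Balancing:** SVM-SMOTE on the training rows only. A linear SVM
   locates the minority-class support vectors (the boundary region); each
   synthetic point interpolates between such a seed and one of its k = 5
   nearest minority neighbours with `u ~ U(0,1)` — interpolation only, so
   every synthetic point lies on a segment between two real minority
   points. A minority class of one falls back to duplication with a
   warning. Synthetic rows inherit the seed point's subject for grouping.
2. **Standardization:** zero mean, unit variance from the balanced
   training set only; skipped for random forest. (Balancing before
   standardization mirrors the protocol's stated order.)
3. **Tuning:** training subjects, sorted by id, are dealt round-robin
   into five groups; every grid point is scored by the mean
   geometric-mean score over the five group folds; ties break toward the
   first grid entry; inner folds missing a class contribute no score.
   Grids: C ∈ {0.01, 0.1, 1, 10, 100, 1000} for logistic regression and
   the linear SVM; depth ∈ {3,4,5,6} for the random forest (Gini,
   √p features per split, 500 trees); 1–3 hidden layers × 100 ReLU units
   for the MLP (Adam, learning rate 0.001, 200 full-batch epochs, seeded
   He initialization, no early stopping).
4. **Scoring:** the winner is refit on the full balanced training set and
   scored on the held-out subject. Decision thresholds: 0 for margin/logit
   models, 0.5 for probabilities.

Test predictions are pooled across folds into one confusion matrix
(sensitivity, specificity, accuracy, geometric-mean score
$\sqrt{\text{sens}\times\text{spec}}$) and one ROC/AUROC over pooled
decision scores — pooling rather than per-fold averaging because a single
held-out subject often lacks one class, leaving per-fold AUROC undefined.
Model implementations: `e1071::svm` (linear kernel), `ranger` (depth-
limited Gini forest), an exact IRLS/Newton ridge-penalized logistic
regression written for the C parameterization, and a small in-package
ReLU/Adam network (no installed R package provides multi-hidden-layer
ReLU networks). Every stochastic step draws from a seed derived from the
run seed and the fold label, so a fixed seed reproduces results
bit-for-bit.

**Feature importance** uses a sampling permutation estimator of
interventional Shapley values on the decision score: random feature
orderings are walked while absent features are filled from sampled
background rows (20 per ordering, 64 orderings by default). For a linear
model this reduces exactly to `coef × (x − mean(background))`, which the
tests verify; features are ranked by mean absolute attribution.

## 7. The synthetic cohort

`synthetic_config()` encodes the emulated study conditions: 19 subjects,
normal (23 °C) and cold (10 °C) days, a 5-minute baseline then five
sessions every 30 min, tasks CDS 2 / PRO 1.5 / GNG 2.5 / SPD 3 / SRT
1.5 min with 30 s gaps, EDA at 4 Hz, ECG at 256 Hz.

* **EDA:** tonic level U(2, 12) µS with slow drift, Poisson SCRs at
  3/min (normal) vs 1.5/min (cold) with amplitudes U(0.05, 0.4) vs
  U(0.02, 0.15) µS — cold exposure attenuates electrodermal activity —
  plus 0.003 µS sensor noise.
* **Heart rhythm:** per-condition means 70 (normal) / 75 (cold) bpm with
  a 3 bpm between-subject SD; RMSSD targets 47 / 44 ms reached by a
  three-iteration jitter-variance calibration; a 0.25 Hz sinusoidal
  modulation of 36 ms amplitude plants ≈ 650 ms² of HF power, matching
  the magnitudes the features should sit at.
* **Reaction times:** subject × task baselines U(400, 1200) ms, session
  shifts N(0, 25 ms), lognormal session-summary noise of 30 ms
  (right-skewed, as reaction times are), and a latent per-session
  *strain* u ~ U(0,1) in the cold that adds up to 120 ms to the true
  session mean **and simultaneously** raises heart rate (up to 10 bpm)
  and SCR rate/amplitude. This coupling is what makes deteriorated
  sessions physiologically recognizable; its strength was chosen so the
  strain term dominates the session noise, giving the normal-vs-
  deteriorated feature contrasts their expected signs without making the
  problem trivially separable.
* **Ground truth:** SCR event times/amplitudes, per-session HR/RMSSD
  parameters, the noiseless reaction-time means, and the deteriorated
  flags obtained by applying the labeling rule to those noiseless means.
  With `rt_noise_sd = 0` the labeling stage reproduces the flags exactly.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: motion and pressure artifacts (absent by
design; the feature chain has no artifact rejection), full ECG morphology
(P/T waves, ectopy; the synthetic beat is a clean R spike, so the peak
detector's real-world robustness is untested), shivering EMG
contamination of EDA, circadian drift, and the actual trial-level
reaction-time distributions of the tasks, for which only session
summaries are modeled. Classifier scores on synthetic cohorts are a check
of protocol correctness, not a forecast of real-data performance.

## 8. Numerical conventions and test scale

* Windows are half-open at native sampling rate; a 60 s window at 4 Hz is
  exactly 240 samples.
* All times are seconds relative to the recording start; epochs live only
  in file headers.
* Readers reject NaN-bearing input outright; writers are deterministic,
  and the pipeline manifest records MD5 checksums of every artifact.
* Grid-search ties break toward the first grid entry; SCR peak conflicts
  within 1 s break toward the larger peak; a value exactly at the
  deterioration threshold is normal.
* Derived seeds (a small LCG hash of the run seed and stage labels) keep
  independent stages on independent random streams while staying inside
  32-bit integer range.

The test suite exercises the pipeline at deliberately modest sizes — e.g.
decomposition windows of 2–10 minutes, cohorts of 2–19 subjects,
LOSO problems of 8–16 subjects × 6–8 segments, 10⁴–10⁵ Monte-Carlo
draws for the distributional checks — sizes chosen so the whole suite
runs comfortably on one CPU while every property is still measured, and
stated here so results can be reproduced at exactly those scales.

## 9. Known limitations

* The decomposition's chunked mode refits the tonic spline per chunk;
  tonic estimates can disagree slightly across chunk seams.
* TVSymp's raised-cosine bank under-weights tones that fall exactly at
  component crossover frequencies (gain 0.5 + 0.5 in amplitude from the
  two neighbours applies to in-phase reconstruction; the envelope at a
  crossover can dip by a few percent).
* The Cohen's d CI is a large-sample approximation.
* The MLP trains full-batch; on much larger feature tables mini-batching
  would be preferable.
* The labeling rule's finite-sample exceedance probability (1/3, see the
  labeling section above) is
  a property of the design being implemented, not a defect of the
  implementation — but it limits the interpretation of deteriorated
  fractions as error rates.
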