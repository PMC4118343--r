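---
title: "Respiration monitoring from chest accelerometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiration monitoring from chest accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathclass)
```

## The problem

A triaxial accelerometer strapped to the sternum measures, on top of the
constant gravity projection, the small tilt of the chest wall that
expansion and contraction of the rib cage produce. After low-pass
filtering, that tilt tracks the lung-volume curve closely enough that the
count of its local maxima per minute is the respiration rate, and that
windowed statistics of the three axes discriminate clinically meaningful
breathing patterns: normal breathing, bradypnea (regular but slower than
normal, here < 12 breaths/min), tachypnea (regular, > 20 breaths/min),
Cheyne-Stokes respiration (crescendo–decrescendo volume modulation
separated by apnea), Kussmaul breathing (rapid, deep and laboured) and
Biot's respiration (bursts of uniform rapid breaths separated by apnea).

`breathclass` implements the full chain: sensor calibration, filtering and
resampling, rate estimation, windowed feature extraction including
Approximate Entropy, a dual-form SVM, a six-leaf hierarchical classifier,
and the binary healthy-vs-impaired evaluation metrics — together with a
seeded simulator that stands in for clinical recordings, which for the
emulated trial protocol were never publicly deposited.

## Sensor calibration

The corrected reading is an affine map of the raw reading,
$y = [w \,|\, 1]\,X$, with $X$ a $4\times3$ matrix holding a $3\times3$
gain block over a $1\times3$ offset row (12 parameters). Captures at six
stationary orientations, where the true input is a unit gravity vector
along $\pm$ each axis, give an overdetermined system solved by least
squares. Two notes:

* The classic normal-equation formula omits the constant column; the
  offsets are only estimable from the augmented design $[w \,|\, 1]$,
  which is what `fit_calibration()` uses — via QR, not an explicit
  inverse, because the contract is least-squares optimality, not a
  factorization.
* More than six captures are accepted; the same equations strictly
  generalize.

On noise-free synthetic batches the generating model is recovered to
solver precision (the acceptance suite requires $\le 10^{-6}$).

## Preprocessing

**Filtering.** Breathing at rest lives below about 1 Hz, so each axis is
filtered with an order-10 Butterworth low-pass at 1 Hz. The filter is
designed directly in second-order sections (bilinear transform of the
analog prototype), which stays stable at this order with a cutoff far
below Nyquist, and is applied forward–backward. Zero-phase filtering is a
deliberate choice: downstream synchronization by cross-correlation assumes
the filter adds no group delay.

**Sampling-rate mismatch.** Loggers rarely run at their nominal rate; a
sensor configured at 50 Hz that actually logs near 52.5 Hz accumulates a
lead of $52.5/50 - 1 = 0.05$ s per second against a reference channel.
`estimate_measured_rate()` discovers the real rate by counting samples per
window of true time; `rational_resample()` then approximates the ratio by
a small fraction via continued-fraction convergents (21/20 for 52.5/50,
denominator capped at 1000), upsamples, applies a windowed-sinc
anti-aliasing FIR and decimates. Reference (spirometer-style) channels are
smoothed with a centered window-30 moving average — the most common
reading of "smoothed with window size 30", documented here as an
interpretation.

**Rate estimation.** The rate is 60 × (count of local maxima) / window.
Raw local maxima are hopeless on noisy data, so two gates are applied: a
minimum peak distance of 0.4 s (a 150 breaths/min physiological ceiling)
and a minimum topographic prominence of 10% of the window's amplitude
range. The breathing axis defaults to the axis with the largest spectral
power in 0.1–1 Hz, configurable, since the convention is otherwise
unstated.

## Features

A 10-s window shifted by 2 s yields `floor(duration / shift)` windows with
truncated tails — 60 windows for a 2-minute recording, 30 for 1 minute.
This bookkeeping is load-bearing: with a stratified 70/30 split it
reproduces the per-subject trial counts (42 training/18 test windows per
2-minute class, 21/9 per 1-minute class, hence 168 training trials for the
four-pattern group and 72 impaired test trials per subject).

Per window the channels are the raw axes, the magnitude
$\sqrt{x^2+y^2+z^2}$, DC-removed axes, and z-scored axes. The candidate
pool is Mean/SD/Max/peak-count on raw axes and magnitude, Energy
($\sum s_i^2$) on DC-removed channels and magnitude, Approximate Entropy
on normalized channels, and the three inter-axis Pearson correlations —
26 features. The windowed SD uses the population ($1/n$) normalization as
the feature tables print it, while `cohort_stats()` uses the sample
($1/(n-1)$) form, which is the one that reproduces the published cohort
SD of ages (11.9026); both conventions are intentional and documented.
"Normalized" is read as z-score (not min–max), flagged as a choice.

**Approximate Entropy.** With template length $m$ and tolerance $r$,

$$\mathrm{ApEn} = \frac{1}{n-m+1}\sum_i \ln C_i^m -
                  \frac{1}{n-m}\sum_i \ln C_i^{m+1},$$

where $C_i^m$ is the fraction of templates (self-match included, the
classic Pincus convention) within Chebyshev distance $r$ of template $i$.
Defaults $m = 5$, $r = 0.15$ on z-scored channels, where an absolute
tolerance of 0.15 equals 0.15 raw-signal standard deviations. Constants
give exactly 0; the implementation is vectorized over the pairwise
distance matrix and is checked against a brute-force double loop to
$10^{-10}$.

## The SVM and the hierarchy

The binary SVM solves the Lagrangian dual of the maximal-margin problem
with kernels linear, polynomial degree 3 ($(x^\top y + 1)^3$) and RBF
($\exp(-\lVert x-y\rVert^2/2\sigma^2)$, $\sigma = 1$). Three choices the
formulation leaves open:

* **Soft margin, $C = 10^3$.** The printed formulation is hard-margin; a
  large but finite box keeps noisy feature sets solvable and recovers the
  hard margin on separable data.
* **Feature standardization** before kernel evaluation, stored with the
  model — without it $\sigma = 1$ is meaningless across features whose
  scales differ by orders of magnitude.
* **Solver.** `quadprog` on the dual, with a growing ridge when the kernel
  matrix is degenerate, followed by an exact re-solve of the KKT
  equalities on the identified free set (removing the ridge-induced bias).
  The contract — KKT satisfied to tolerance, $\sum_i \alpha_i y_i = 0$ —
  is what the tests check, against an independent brute-force active-set
  enumeration on small instances.

The hierarchy is a five-branch, six-leaf binary tree. The root separates
the four 2-minute patterns from the two 1-minute patterns (forced by the
printed 168/42 trial counts); below the root the slow patterns
({normal, bradypnea}) split from the fast ones
({tachypnea, Cheyne-Stokes}), then leaves. The sub-root topology is an
inference — the published figure is not textually recoverable — so the
tree is config-overridable. Per branch, **every unordered pair** of
candidate features is evaluated by training an SVM and scoring it on the
same training rows ("training set = validation set", exactly as the
protocol describes); this is acknowledged as optimistic, and an optional
cross-validated scorer exists but is off by default to match the described
procedure. Ties break lexicographically. Pair size is fixed at two, as in
every published branch.

## Evaluation

Binary evaluation collapses predictions to healthy (normal; positive)
versus impaired (anything else; negative):
sensitivity $= TP/(TP+FN)$, specificity $= TN/(TN+FP)$, accuracy
$= (TP+TN)/\text{total}$, G-mean $= \sqrt{\text{sens}\cdot\text{spec}}$.
Case 1 trains one classifier per subject and averages metrics and counts
(fractional counts are therefore legal); case 2 trains a single pooled
classifier. Metrics are kept at full precision; rounding is display-only.
A known quirk of the published per-table G-mean column for the pooled
model is inconsistent with its own printed sensitivity/specificity under
the G-mean formula; this package follows the formula.

## The simulator: what it emulates, and what it does not

Each breath is a raised-cosine cycle $a\,(1-\cos 2\pi t/T)/2$ — smooth,
zero at breath boundaries, exactly one maximum at the midpoint, so
ground-truth peak times are known exactly. Pattern structure:

* Cheyne-Stokes: per-breath amplitudes follow a sinusoidal
  crescendo–decrescendo over the active phase, then a flat apnea of at
  least 3 s. The envelope scales whole breaths (evaluated at breath
  midpoints) rather than multiplying samplewise, so the exact peak-time
  guarantee survives. Defaults put the full cycle (6-s active + 4-s
  apnea) inside one 10-s analysis window, matching the protocol's stated
  rationale for the window length; the emulated trial tables likewise
  show fast overall Cheyne-Stokes rates.
* Biot's: bursts of `burst_breaths` constant-amplitude breaths (default
  4 at 40 breaths/min) alternating with apnea of at least 3 s.
* Kussmaul: fast (28/min) and deep — amplitude 2.5× a normal breath.

The accelerometer forward model is gravity DC plus per-axis coupling gains
times the mean-centered waveform **in native amplitude units** (g per unit
breath amplitude, order 0.01 g), plus i.i.d. Gaussian noise per axis; the
result is distorted by the inverse of a known calibration model (so the
calibration fit is exercised end to end) and sampled at the measured
(52.5 Hz) rather than nominal (50 Hz) rate. Keeping native amplitude
units is deliberate: z-scoring each recording would erase breath depth and
make Kussmaul — *defined* by its depth — structurally indistinguishable
from tachypnea.

The default study is 11 subjects: 2-minute recordings of the first four
patterns, 1-minute recordings of Kussmaul and Biot's, with two child
subjects performing only two patterns each (ages default to the emulated
cohort: mean 26.54, sample SD 11.9026 years). Rates are drawn per subject
from non-degenerate, physiologically sensible ranges per pattern; all
randomness flows from one master seed through a deterministic hierarchy,
so a configuration reproduces its study byte for byte.

What the simulator does **not** emulate: real lung mechanics and air
volumes, sensor drift and motion artefacts, posture changes, inter-breath
variability beyond i.i.d. noise, or the true inter-subject variability of
patient populations. A green end-to-end test therefore establishes that
the pipeline's machinery is correct on data with the protocol's stated
structure — not that the published field accuracies would replicate on
clinical recordings.

## Numerical choices and degenerate inputs

* Zero-phase filtering pads by odd reflection (12 time constants) before
  the forward–backward pass; edges are exact to ~$10^{-5}$ for constants.
* The resampler extends the signal symmetrically before the polyphase
  FIR, so edge roll-off does not eat breathing peaks.
* Zero-variance channels normalize to all zeros with a message (they
  carry no information either way); correlations with a constant channel
  are an error, and feature windows that error out are dropped with a
  logged count.
* Cross-correlation ties break toward the smallest absolute lag.
* Flat signals have zero peaks, hence 0 breaths/min, by definition.

## Runtime scaling in the tests

Exhaustive pair selection trains $\binom{26}{2} = 325$ SVMs per branch;
with per-subject row counts this is ~1 minute per subject on one CPU. The
acceptance suite therefore runs the end-to-end case-1 evaluation on five
subjects of the default protocol rather than all eleven — a runtime
scale-down, stated here; the per-subject geometry is unchanged.

## Known limitations

* Trailing windows are truncated (the bookkeeping that reproduces the
  printed trial counts requires it), so a handful of 2–8-s windows per
  recording carry degraded features and bound attainable accuracy.
* Feature-pair selection scored on its own training rows overestimates
  branch accuracy; use `scorer = "cv"` for an honest estimate.
* The dual QP is dense: training is practical to a few thousand windows,
  not beyond.
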