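---
title: "Methods: behaviour classification from collar accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behaviour classification from collar accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collarHMM)
```

This vignette is the package's account of its methods: the signal model,
the classifier, the choices that were genuinely open and how they were
settled, and what the synthetic data can and cannot tell you about real
collars.

## The signal model

A neck-mounted tri-axial accelerometer measures, in units of g, the sum
of gravity projected onto the sensor axes and the acceleration generated
by movement, plus noise. The gravitational part changes with posture
(head up, head down, lying) on a time scale of seconds; the movement part
oscillates at gait frequencies. For large grazing ungulates the motion
band is taken to extend to about 5 Hz, which at the logger's 10 Hz
sampling rate is exactly the Nyquist limit — hence the default
`sensor_params(rate_hz = 10, bits = 8, range_g = 8)`.

`estimate_static()` separates the two components with a centred running
mean. The span is a *tunable* parameter (`span_s`, seconds; default 5):
long enough to average several gait cycles out of the gravity estimate,
short enough to track posture changes. The support is the nearest odd
sample count, `2 * floor(span_s * rate / 2) + 1` — 51 samples at the
defaults — so the window is symmetric about each sample. At the first and
last 25 samples the window *shrinks* rather than dropping samples or
padding; processing therefore never changes the sample count, at the
price of noisier static estimates within 2.5 s of the ends.

From the static vector, `roll = atan2(sY, sZ)` and
`pitch = -atan(sX / sqrt(sY^2 + sZ^2))`, stored in radians (degrees only
at I/O). Two degenerate cases are handled explicitly: when
`sY = sZ = 0` with `sX` nonzero the pitch takes its limiting value
±π/2, and an all-zero static vector (possible after aggressive
quantization near free fall) maps to roll = pitch = 0 with the count of
such samples recorded in the `n_degenerate` attribute rather than an
exception — a long deployment should not die on a handful of degenerate
samples.

## Collar rotation

A collar free to rotate about the neck rotates the sensor about its X
axis, shifting roll by some offset α while leaving pitch and the norm
essentially alone. How to estimate α from data was an open choice; the
package uses the **circular median of the roll series** (rotate by the
circular mean, take the linear median of wrapped residuals, rotate back)
minus a reference roll, default 0, i.e. the sensor hanging in its nominal
ventral position. The median is preferred to the mean because activity
bursts swing roll hard for seconds at a time; a location estimate robust
to those bursts tracks the slow geometry of the collar instead. With
`window_s = NULL` one constant offset per individual is returned; with a
window (default consideration: 300 s, and never shorter than the
smoother span) block-wise medians are unwrapped and interpolated into a
slowly varying series.

The correction multiplies the raw axes by the rotation matrix about X
with the estimated offset, in the direction that returns an observed
roll of α to the reference. One sign convention had to be fixed here:
the package defines "offset +α" as "the roll series reads +α", and
`apply_rotation_correction()` undoes exactly that, which makes
estimate → correct → re-estimate land at zero (idempotence) and makes a
simulator-injected +30° offset come back as +30°. The norm is preserved
to machine precision because the correction is a proper rotation.

A second open choice: the corrected axes are fed **back through** the
static/dynamic/angle computation, so all downstream features describe a
fixed sensor frame. The alternative — correcting only the raw axes and
keeping features from the uncorrected frame — would leave roll-based
features carrying the collar offset.

## Windows and features

Labelled traces are segmented into fixed windows (`width_s` ∈ {2, 3, 5} s
in the shipped experiments, non-overlapping by default; `overlap` is
configurable in [0, 1)). A window is kept only if at least `purity`
(default 1.0) of its samples carry one training-class label other than
"unlabelled". Pure windows reproduce the rule that behaviours shorter
than the window cannot contribute training windows (a sub-2-s bout never
fills a 2-s window), without introducing mixed-label noise; the
threshold is a parameter precisely so that this choice can be studied.

Each window yields six statistics per channel: mean, min, max, median,
IQR and sd. Two conventions are fixed for reproducibility: quantiles use
**linear interpolation between order statistics** (R's default type 7),
so IQR of {1, 2, 3, 4} is 3.25 − 1.75 = 1.5; and sd is the **sample
(n − 1)** standard deviation. The default channel set is the raw, static
and dynamic axes plus roll (10 channels, 60 candidate features); pitch
and norm are computed and available but excluded from the default
candidates, since orientation-magnitude summaries invite overfitting
once the frame has been fixed by the collar correction. A curated
12-feature preset (`preset_features_12()`) covering posture (roll
median/spread, static surge and sway) and gait (dynamic surge and heave)
can be used instead of data-driven pruning; `prune_correlated()`
(threshold |r| > 0.9, dropping the member of the worst pair with the
larger mean absolute correlation, ties to the alphabetically later name)
and `forward_feature_selection()` (best pair first, then greedy additions
while held-out accuracy strictly improves) are the data-driven route.

## The classifier

`behavior_hmm()` treats the training labels as the hidden states of a
first-order Markov chain with multivariate-normal emissions. With full
labels the maximum-likelihood problem factorises, so the fit is closed
form and exact:

* transitions: counts within contiguous window sequences, plus a
  **pseudocount** (default 1) so rare behaviours never get zero mass;
* initial distribution: run-initial label frequencies (same pseudocount);
* emissions: class-wise sample means and covariances with a **ridge** of
  `1e-6 ×` the mean within-class variance added to the diagonal — 8-bit
  quantization can make a feature near-constant within a class, and the
  ridge keeps the covariance positive definite.

Sequence structure matters: windows dropped at segmentation break a
trace into separate sequences (`seq_id`), the initial distribution
applies at every break, and no transition is counted across a break.
All probability computation is in log space (log-sum-exp in the forward
recursion; no scaling-factor variant), Viterbi ties break toward the
alphabetically first state, and an optional Baum–Welch pass
(`em = TRUE`, tolerance 1e-6 on the log-likelihood, at most 100
iterations) refines the closed-form fit for parity with unsupervised
practice. Supervised closed form is the default because it is exact,
fast and deterministic.

Two guards encode the evaluation contract. `predict()` refuses an
individual that was in the training set (LOSO would be broken
silently otherwise; `allow_overlap = TRUE` exists for training-set
diagnostics). And a class with fewer than 2 windows is an error
(covariance undefined), while fewer than `D + 2` windows draws a warning
— the ridge carries the fit, but the estimates are poor and merging
classes is the better answer.

## Baselines and metrics

The random forest and radial SVM are deliberately off-the-shelf
(`randomForest`, `e1071`); the package fixes only their contracts.
RF: `mtry` tuned over 1…min(10, D) by mean LOSO accuracy, 50 trees by
default (500 available for exploration). SVM: C over
{0.25, 0.5, 1, 2, 4} crossed with γ = (median-heuristic value) ×
{0.5, 1, 2}; features standardized per training fold with the test fold
transformed by the training parameters only. When a training fold
contains a single individual (the 2-individual LOSO edge case) inner
tuning is undefined and the drivers fall back to untuned defaults.

Confusion matrices pool predictions across folds (each individual is
predicted exactly once, by a model that never saw it). Per-class
sensitivity and precision are the usual row/column ratios;
behaviour-specific *accuracy* is the **one-vs-rest** accuracy
`(TP + TN) / N` — stated prominently because other conventions exist.
Metrics with empty denominators (a class with no true or no predicted
windows in a fold) are reported as flagged `NA`, never as 0, so rare
classes are not silently deflated. Cohen's kappa uses the margins of the
pooled matrix and is `NA` when expected agreement is 1.

## What the simulator emulates — and what it does not

The generator exists so that every stage is testable end to end. Each
behaviour has a gravity direction given by a head/neck pitch angle, a
surge-axis oscillation (amplitude, frequency ≤ 5 Hz), white noise, an
exponential mean bout duration, and an occupancy weight. Bouts
alternate with exponential dwell times — memoryless bouts make the
window-label process first-order Markov, matching the classifier's
assumption (semi-Markov dwell distributions were considered and
deferred). The next-bout weights are solved by a small fixed point so
that long-run time-in-behaviour fractions converge to the occupancy
weights. Samples are quantized by round-to-nearest onto the
`2 * range / (2^bits − 1)` grid, saturating at ±range.

The default ethogram is deliberately imbalanced (inactivity 0.35 and
grazing 0.30 dominate; browsing high 0.05 and trotting 0.03 are rare)
and deliberately hard: the browsing classes sit only ~20° apart in head
angle before individual offsets, because on a neck sensor the difference
between browsing low and high is a modest neck-angle change. Realism of
the *within*-class distributions comes from three mechanisms chosen
once and frozen: a log-normal AR(1) amplitude envelope (log-sd 0.4,
time constant 2 s) and a phase random walk (0.15 rad/sample), because
gait is not a constant sinusoid; and between-individual effects (head
angle offsets with sd 8°, log-normal amplitude factors with cv 0.35),
because individual variation is what makes LOSO hard. Under these
conditions the synthetic LOSO accuracies land in the 70–90% range with
rare-class sensitivity suffering for the per-window classifiers — the
regime of interest — rather than at ceiling.

What the simulator does **not** emulate: harmonic-rich gait waveforms,
behaviour-dependent noise colour, transitions biased by time of day (no
day/night structure at all), GPS or temperature channels, and sensor
mounting differences beyond a roll offset. Passing tests on synthetic
data therefore demonstrate the pipeline's correctness and its
qualitative behaviour under imbalance and serial dependence; they do not
certify accuracy numbers on real animals.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script use sizes chosen to make
their statistics meaningful while keeping a full run in minutes: the
exhaustive-enumeration checks cover 200 random instances with at most 3
states and 7 windows (all 3⁷ paths enumerable exactly; agreement to
1e-8); parameter recovery uses 5,000 windows from a known 3-state model
(3-standard-error bands); the model comparison uses the default dataset
of 6 individuals × 900 s (≈ 2,500 2-s windows), which is enough for
~100–170 windows of each rare class. Norm invariance is asserted at
1e-12 relative error; collar-offset recovery at 2°; the JSON model
round trip is lossless (17 significant digits).

## Known limitations

* The collar correction handles rotation about X only; slippage that
  tilts the sensor about Y or Z is not modelled.
* The HMM assumes normal emissions; heavy-tailed features (e.g. max_dX
  during erratic movement) violate this, and the model compensates only
  through covariance inflation.
* `K` equals the number of observed classes — there is no hidden-state
  selection, and no covariates on the transition probabilities.
* With very small training sets the ridge-stabilised covariances of
  thin classes make likelihoods unreliable; the warning threshold
  (`D + 2` windows) is a floor, not a recommendation.
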