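# collarHMM

Classifying fine-scale behaviour of grazing ungulates (reindeer being the
motivating case) from collar-attached tri-axial accelerometers. Neck
collars record acceleration in three axes — X (surge, fore–aft), Y (sway)
and Z (heave) — at 10 Hz, and the goal is to recover what the animal was
doing (grazing, browsing low or high, inactivity, walking, trotting,
other) window by window, including on individuals the model has never
seen. That last requirement is what makes the problem hard: collars
rotate around the neck, and individuals differ in posture and gait, so
honest evaluation must be leave-one-subject-out (LOSO).

## What the package does

**Signal decomposition.** The static (gravitational) component of each
axis is a centred running mean over a 5-s span — 51 samples at 10 Hz,

    sX_i = (1/51) * sum_{j=i-25}^{i+25} X_j

— and the dynamic component is the absolute residual `dX_i = |X_i - sX_i|`.
From the static vector the package derives the Euler angles
`roll = atan2(sY, sZ)` (±π) and `pitch = -atan(sX / sqrt(sY² + sZ²))`
(±π/2), and the orientation-free magnitude `norm = sqrt(X² + Y² + Z²)`.

**Collar-rotation correction.** A rotated collar shifts the roll angle.
The offset α is estimated as the circular median of roll (robust to
activity bursts) and undone by the rotation matrix about X,

    R_x(φ) = [[1, 0, 0], [0, cos φ, −sin φ], [0, sin φ, cos φ]],

applied so that a static vector observed with roll α returns to the
reference orientation. The norm is invariant under this correction.

**Features.** Labelled traces are cut into fixed non-overlapping windows
(2, 3 or 5 s); each window gets six time-domain statistics (mean, min,
max, median, IQR, sd) per channel. A curated 12-feature set
(`preset_features_12()`) and data-driven correlation pruning
(`prune_correlated()`) plus greedy forward selection
(`forward_feature_selection()`) are both available.

**The model.** `behavior_hmm()` fits a supervised hidden Markov model:
the behaviour classes are the hidden states of a first-order Markov
chain, and each state emits multivariate-normal feature vectors. With
labelled windows the maximum-likelihood fit is closed form — transition
counts (plus a pseudocount so rare behaviours keep mass), run-initial
frequencies, class-wise means and ridge-regularised covariances.
Likelihood uses the log-space forward algorithm; decoding uses Viterbi;
an optional Baum–Welch pass (`em = TRUE`) refines the closed-form fit.
Because the chain carries information between windows, the HMM is
noticeably better than per-window classifiers at rare behaviours.

**Baselines and evaluation.** LOSO-tuned random forests (mtry over
1…min(10, D)) and radial SVMs (C ∈ {0.25, 0.5, 1, 2, 4}, γ from the
median heuristic × {0.5, 1, 2}, per-fold standardization) serve as
comparators; `run_experiment()` evaluates every model × window size with
pooled confusion matrices, per-class sensitivity/precision/accuracy/F1,
overall accuracy and Cohen's kappa.

**Synthetic data.** `simulate_dataset()` generates multi-individual,
behaviour-annotated traces with posture-dependent gravity, behaviour-
dependent oscillation (≤ 5 Hz), within-bout amplitude envelopes, 8-bit
±8 g quantization, natural class imbalance, between-individual variation
and optional collar drift — so the whole pipeline is testable without
field data.

## Worked example

```r
library(collarHMM)

ds   <- simulate_dataset(n_individuals = 4, duration_s = 600, seed = 5)
proc <- annotate_samples(process_trace(ds$trace), ds$annotations)
tab  <- window_features(proc, width_s = 2)

fit <- behavior_hmm(tab[tab$id != "ind04", ], features = preset_features_12())
print(fit)
#> Supervised Gaussian-emission hidden Markov model
#>   states   : 7 (browsing_high, browsing_low, grazing, inactivity, other, trotting, walking)
#>   features : 12 (m_roll, IQR_roll, mean_sX, sd_sX, mean_dX, max_dX, m_Y, IQR_Y, min_sY, max_sY, sd_dZ, mean_dZ)
#>   fitted on: 855 windows from 3 individual(s)
#>   self-transition probabilities:
#> browsing_high  browsing_low       grazing    inactivity         other
#>         0.750         0.908         0.977         0.986         0.625
#>      trotting       walking
#>         0.696         0.860

pred <- predict(fit, tab[tab$id == "ind04", ])   # LOSO guard enforced
confusion(pred$label, pred$pred, classes = fit$states)
#> overall accuracy 86.8%, kappa 0.779
```

The self-transition probabilities show the behavioural stickiness the
chain exploits (grazing and inactivity bouts persist; trotting is brief).
The held-out individual is decoded at 86.8% — dominant behaviours are
near-perfect while rare ones on an unseen individual remain hard, which
is exactly the LOSO picture on real collar data. A full comparison grid
is one call:

```r
report <- run_experiment(proc, window_sizes = c(2, 3, 5))
print(report)          # overall accuracy and kappa per model x window
report_table(report)   # wide per-class Se/Pr/Ac table in percent
```

An end-to-end configurable run (dataset, features, models, report and a
reproducibility manifest written to disk) is
`run_pipeline(default_config(), "out/")`, also reachable from a shell via
`inst/scripts/collarHMM-pipeline.R`.

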