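---
title: "Methods: individualized weight estimation from insole sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized weight estimation from insole sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

A pair of instrumented insoles reports, per foot, 16 plantar pressures
(N/cm²), the total ground-reaction force (N), inertial channels and the
center of pressure — 51 columns per recording including the timestamp.
At quiet standing the combined total force is proportional to the
supported weight, so weight estimation is, in the ideal case, a
one-feature inversion. Real recordings break the ideal in three ways
that structure the whole pipeline: channels a participant never loads
read exactly zero (and barely-loaded channels read near-zero),
recordings differ in length, and load distributions are so individual
that a model pooled across people cannot separate participants whose
sensor ranges overlap. The package therefore corrects channels with a
per-participant adaptive bias, normalizes instance counts with dynamic
windowing plus trimmed-mean aggregation, and trains one regressor per
participant on recordings labeled `body_weight + carried_weight` (the
protocol grades total weight with carried dumbbells, e.g. 0, 2, 3, 5, 7,
9, 11, 13 lbs).

## Model and procedure

**Adaptive bias.** For feature $j$ and weight-class index
$i \in \{1..L\}$ the correction is $B_{ji} = m_j \, i / L$, with $m_j$
the minimum strictly-positive value of feature $j$ among samples of the
*maximum* carried weight, falling back to the next-highest weight until
a non-zero minimum exists. Corrected readings are
$S'_{ji} = S_{ji} + B_{ji}$: in FAB mode for every sample, in ZRAB mode
only where $S = 0$ exactly. Three properties matter: the shift increases
with $i$ (restoring positive weight–feature correlation on corrupted
channels), it is per-feature (channels have different scales), and it is
per-participant (load patterns are individual). The bias is fit on
training iterations only and reused frozen on held-out iterations;
applying it twice is an error the pipeline enforces with an
`bias_applied` attribute.

**Zero detection is exact.** ZRAB updates only samples equal to 0.0 — no
epsilon band — because the mode's known weakness is precisely that
near-zero readings escape it; an epsilon band would erase the
FAB-vs-ZRAB contrast the ablation measures.

**Dynamic windowing.** With sequence length $L_{data}$ and user
parameters $l_{samples}$ and $olap_{init}$:
$Win_{init} = L_{data}/l_{samples}$,
$Olap_{new} = olap_{init} \cdot Win_{init}$,
$Win_{new} = (L_{data} + Olap_{new} Win_{init})/l_{samples}$. The two
"window length" symbols are resolved as: $l_{samples}$ is the
user-chosen instance-count parameter, $Win_{init}$ the derived window
size in samples — the only reading under which a larger $l_{samples}$
yields smaller windows and more training instances, the documented
behavior. $Win_{new}$ and $Olap_{new}$ are generally fractional;
boundaries use length $\mathrm{round}(Win_{new})$ (floored at 1), stride
$\mathrm{length} - \mathrm{round}(Olap_{new})$ (floored at 1), and the
trailing partial window is dropped rather than padded — a short tail
would contribute a noisy aggregate. Windows never cross recording
boundaries.

**Trimmed-mean aggregation.** Each (window, channel) cell is the
arithmetic mean after dropping $k = \lfloor \alpha n / 100 \rfloor$
values from each end of the sorted window ($\alpha = 0$: mean;
$\alpha = 50$: median). Ties keep duplicates (multiset semantics); if
$2k \ge n$, $k$ is reduced to $\lfloor (n-1)/2 \rfloor$ with a warning,
which preserves the median semantics of $\alpha = 50$ on even lengths.
The 34 raw channels are corrected and aggregated first; the 6
synthesized features (per-foot pressure sums, combined pressure sum and
average over 32 cells, combined force sum and average over both feet)
are recomputed from corrected values so they stay consistent with their
definitions. The exact membership of the six synthesized features
admits several readings of "sum and average … individually and
combined"; this package fixes the six above.

**Personalized regression.** The default learner is an
extremely-randomized-trees regressor implemented in compiled code
(candidate splits draw one uniform cut point per candidate feature;
trees are grown on the full sample until pure, `mtry` defaults to all
40 features). Only this learner ships: gradient-boosting alternatives
are recognized names that fail with an informative error when their
packages are absent. The 80/20 train/validation split and the CV folds
are stratified by carried weight so every weight class appears in
training. Determinism: one integer seed fixes the split, folds and
forest bit-for-bit.

**Metrics.** From $e_i = y_i - \hat y_i$: MAE, MSE, RMSE$=\sqrt{MSE}$,
$R^2 = 1 - \sum e_i^2 / \sum (y_i - \bar y)^2$ with $\bar y$ the mean of
the *supplied ground truths* — on a held-out set this is the test-set
mean, the literal reading of the formula — and MAPE stored
as a fraction (the CLI prints percent). Cohort rows are unweighted means
of per-participant metrics, so the averaged RMSE is the mean of RMSEs,
not the root of the averaged MSE.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `bias_mode` | `"fab"` | ablation-selected correction mode |
| `l_samples` | 100 | windowing instance-count parameter (unitless) |
| `olap_init` | 0.2 | initial overlap rate |
| `alpha` | 15 | trim percentage per window |
| `train_fraction` | 0.8 | train share within training iterations |
| `cv_folds` | 5 | CV folds (0 skips CV) |
| `n_trees` | 100 | forest size |

The defaults are the operating point the preprocessing ablation selects
(full bias, sample length 100, 15% trim); `run_experiment()`'s default
protocol trains on iterations 1 and 3 and tests on iteration 2, the
three-iteration controlled design; two-iteration datasets use
`protocol = list(train = 1, test = 2)`.

## The synthetic cohort: what it emulates

Datasets of this kind are private, so the generator is first-class,
tested code. Its stated world, all parameters chosen once on physical
grounds and exposed in `synthetic_participant_spec()`:

* **Weight proportionality**: total force $F = 4.448\,\mathrm{N/lb}
  \times (\text{body weight} + \text{carried weight})$, split over 32
  cells by Dirichlet load shares (concentration 5 ≈ balanced, 0.5 ≈
  skewed/unbalanced participants); per-cell pressure uses a nominal
  10 cm² contact area. The pipeline's tree models are scale-free, so
  only monotonicity matters.
* **Temporal structure**: multiplicative AR(1) noise (coefficient 0.9
  at 50 Hz) with two components — a small common-mode total-load
  fluctuation (sd 0.01: sway and breathing move all cells together, the
  total changes little) and larger independent per-cell redistribution
  noise (sd 0.05).
* **Between-iteration calibration**: sensors are recalibrated at the
  start of every experimental iteration, so each (iteration, sensor)
  draws a persistent gain $N(1, 0.6 \times \mathrm{noise\_sd})$. Without
  this, train and test iterations are identically distributed and any
  mode interpolates held-out data — the single most important realism
  term for honest evaluation.
* **Transient episodes**: stance adjustments (Poisson, one per ~10 s;
  0.2–1 s long) partially unload the insoles (dip factor 0.05–0.6) with
  erratic per-cell scatter. They populate the low-range/near-zero tail
  of every loaded channel — which keeps the bias anchors $m_j$ small
  and feature-scaled — and they are the "noisy, uncorrelated samples"
  that contaminate large aggregation windows and drive the
  sample-length and trim ablation trends.
* **Corruption**: per-(recording, channel) exact-zero dropout
  (probability 0.25 for unbalanced participants, 0 for balanced),
  near-zero "flicker" channels at 0.1–2% of nominal load (what ZRAB
  misses), and outlier rows (probability 0.01, ×3).
* **Plumbing realism**: recordings are 20 s at 50 Hz (1000 samples) per
  weight, written at 6-decimal export precision so files round-trip
  value-exactly; IMU and center-of-pressure channels are stationary
  noise around posture constants — carried through I/O, unused by the
  model.

What it does **not** emulate: biomechanically realistic gait or walking
dynamics, activity-dependent waveforms, temperature/drift effects, or
the empirical magnitudes of any real sensor. A green trend test
therefore establishes that the pipeline responds to these mechanisms as
the method predicts — not that real-data error magnitudes are
reproduced.

One acceptance clause is knowingly red in this world and left red: the
balanced participant's FAB-vs-no-bias gap is not small relative to the
unbalanced participants' gap. Here the weight-indexed shift also
mitigates calibration and episode noise, which hit balanced and
unbalanced participants alike, so the full bias keeps helping balanced
data more than it would on data whose balanced channels are already
cleanly correlated. The test documents the behavior rather than
widening its threshold.

## Numerical choices and degenerate inputs

* Window geometry rounds to nearest (`round`), floors length and stride
  at 1; a sequence shorter than `l_samples` degrades to a single
  full-sequence window with a warning.
* A feature that is zero across *all* weight classes has no non-zero
  minimum: configurable as an error (default) or bias 0 with a warning.
* `evaluate_predictions()` requires non-zero ground truths (MAPE);
  zero-variance ground truth yields `NaN` R² with a warning.
* Forest prediction on training rows reproduces labels exactly when
  leaves are pure — used as a test invariant, not a performance claim.
* The weight-class index used to apply the bias comes from the
  recording's known carried weight, at test time too. This mirrors the
  protocol being reproduced, and it means corrected features carry
  label information; the evaluation is therefore a measure of the
  procedure as specified, not of a deployment where the carried load is
  unknown.
* The regression formalism is written linear-in-features; the fitted
  learner is a tree ensemble. The predictor contract (40-vector → lbs)
  is what the package fixes; the linear form is not actually fitted.

## Known limitations

Hyperparameters of the original best regressor are unreported, so
compiled-forest defaults are used. The generator's noise magnitudes are
conventions, not measurements. Activity recognition, in-motion
estimation, and cross-participant transfer are out of scope; the
"self-retraining" deployment loop is realized as re-running training on
new iterations, not as an online algorithm.
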