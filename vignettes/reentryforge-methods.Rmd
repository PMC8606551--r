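---
title: "Methods: synthetic ischemic substrates, programmed stimulation, and geometric risk classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ischemic substrates, programmed stimulation, and geometric risk classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(reentryforge)
```

# What the package models

Patients recovering from myocardial infarction carry a spatially graded
injury: a dense ischemic core surrounded by a border zone of partially
remodeled tissue. That border zone is the classical substrate for reentrant
ventricular arrhythmia. `reentryforge` implements a desk-scale version of a
combined in-silico / machine-learning risk pipeline:

1. **Geometry** — synthetic ventricular substrates: 2D myocardial sheets
   (fast, used throughout tests and experiments) and voxelized truncated
   prolate-ellipsoid LV shells (for 3D demonstrations), with AHA 17-segment
   maps, rule-based transmural fiber rotation, and an embedded ischemic
   subdomain.
2. **Graded ischemia** — the ischemic region is split into 10–27 concentric
   layers by distance from its outer surface; electrophysiological severity
   increases toward the core.
3. **Layer peeling** — relabeling the outermost k layers as healthy creates
   new "virtual patients" with smaller injuries; a baseline cohort peeled at
   k ∈ {1, 2, 5, 10} becomes an augmented cohort.
4. **Electrophysiology** — a monodomain reaction–diffusion solver with the
   ten Tusscher–Panfilov (2006) human ventricular ionic model (epicardial
   variant), including the ischemic modifications below.
5. **Programmed stimulation** — an adaptive S1–S4 vulnerability protocol at
   the 17 AHA pacing sites classifies each (model, segment) as no reentry
   (NR), unsustained (UR), or sustained reentry (R).
6. **Risk classification** — seven classifiers predict per-segment
   inducibility from four geometric features, and a repeated-split harness
   compares baseline against augmented cohorts.

# Ionic model and ischemic remodeling

The membrane model is the 2006 ten Tusscher–Panfilov formulation with
19 state variables. Ischemia enters through four knobs, set per layer by
`grade_layers()`:

* **Extracellular potassium** `K_o` rises linearly from 7.5 mM in the
  outermost layer to 10 mM in the innermost (a single layer takes 10 mM).
  Elevated `K_o` depolarizes the resting membrane via the Nernst potential
  and slows conduction through sodium-channel inactivation.
* **Current downscaling**: I_Na and I_CaL maximal conductances are reduced
  by 20% over the outer half of the layers and 30% over the inner half
  (ties to the inner zone, so L = 5 splits 2/3).
* **ATP-sensitive K+ current**: `I_KATP = g_KATP · f_ATP · (K_o/5.4)^0.24 ·
  (V − E_K)`, with `f_ATP = 0.0049`. The maximal conductance `g_KATP` is a
  calibration constant: channel-density figures for this current vary
  widely across formulations, so `g_KATP = 1.5 nS/pF` was chosen once such
  that `f_ATP = 0.0049` shortens the healthy APD90 by
  ≈ 19% (target band 10–25%), and not revisited. It is a `cell_params()`
  argument, not a hard-coded constant.
* **Conductivity**: all ischemic tissue is scaled by 0.6 (a uniform 40%
  reduction; a single reduction figure is
  the stated condition, so it is applied uniformly rather than graded).

Two conductance presets exist: `"baseline"` (published defaults) and
`"steep"`, the steep-restitution variant (G_pCa = 0.8666 nS/pF,
G_pK = 0.00219 nS/pF, doubled voltage-gated inactivation time constant of
I_CaL), which promotes APD alternans and wavebreak and is the default for
vulnerability runs.

## A note on the restitution slope

The steep preset is nominally the "restitution slope 1.8" parameter set.
We measure S1S2 restitution (`restitution_slope()`: pace to steady state at
a 600 ms S1 cycle length, deliver S2 after each diastolic interval, report
the maximum finite-difference d(APD90)/d(DI); an S2 response only counts
when it produces a full action potential with overshoot above 0 mV).
This estimator is honest but ill-conditioned near the capture boundary:
with our protocol the steep preset measures ≈ 2.7 by maximum finite
difference and ≈ 2.0 by a smooth monoexponential fit, while the baseline
preset measures ≈ 1.3–1.4. Across defensible protocol variants (stimulus
strength, capture criterion, S1S2 vs dynamic pacing) the steep preset spans
roughly 1.0–2.7. We therefore treat "steep" as a qualitative regime —
robustly steeper than baseline, slope > 1 over a broad DI range — rather
than pinning the preset to a single slope value at high precision, and the
package reports whatever its own protocol measures.

# Tissue solver

`run_monodomain()` advances `dV/dt = ∇·(D∇V) − I_ion − I_stim` by operator
splitting: Rush–Larsen updates for the 12 voltage-gated gates, forward
Euler with analytic buffering for the concentrations, and explicit finite
differences for diffusion on the structured grid (face-averaged
conductances, no-flux boundaries, mixed-derivative terms for rotated fibers
by central differences). Defaults: `dx = 0.25 mm`, `dt = 0.02 ms`; the
diffusion step is automatically sub-stepped when `dt` exceeds the explicit
stability limit `dx²/(4 max D)`.

Numerical choices and their verification:

* Diffusion defaults `D_l = 0.154 mm²/ms`, `D_t = D_l/4` give a planar
  conduction velocity of ≈ 0.7 mm/ms along fibers — mid-physiological. Reported
  tissue conductivities differ substantially across experimental and
  modeling studies, so these literature values are configuration, not
  ground truth.
* Cable physics: scaling conductivity by 0.6 reduces CV by a factor
  measured at 0.74, within 5% of the theoretical √0.6 ≈ 0.775.
* Mesh convergence: on a 15 mm strand CV changes by ≈ 4% between
  `dx = 0.2` and `0.1 mm` (it changes by ≈ 7% between 0.25 and 0.125 mm —
  the default spacing trades a few percent of CV accuracy for speed, which
  is acceptable because protocol outcomes, not absolute CV, are the
  endpoint).
* Conservation: with the reaction switched off the face-flux scheme
  conserves the spatial mean of V exactly for axis-aligned fibers; the
  cross-term scheme for rotated fibers is *not* discretely conservative
  (a known limitation, acceptable at the small fiber-rotation gradients
  used here).
* The stimulus template (10 ms, nominal 100 µA/cm², ~1 mm² footprint) is
  delivered through an electrode-coupling factor of 0.3 → 30 pA/pF
  transmembrane current. Injecting the nominal figure directly as
  transmembrane current density drives the ionic model beyond +200 mV;
  the coupling factor is an explicit, documented conversion calibrated so
  the pulse is comfortably suprathreshold (threshold ≈ 4–5 pA/pF at
  10 ms) yet numerically benign.

# Programmed stimulation protocol

`run_protocol_statemachine()` implements the adaptive protocol: five S1
drive beats at 350 ms cycle length; S2 first coupled at 200 ms and
shortened in 10 ms steps until reentry or capture failure; on failure, S2
is fixed at the last captured interval and S3 starts at 250 ms, likewise
S4; each premature stimulus is followed by a 2000 ms observation window.
Design decisions that are genuinely open and fixed here by convention:

* **Capture** = at least one activation ≥ 5 mm from the electrode centroid
  within 100 ms of the stimulus (local-only excitation is not capture).
* **Sustained vs unsustained**: an episode is `R` when reexcitation occurs
  *and* activity persists into the final 200 ms of the observation window;
  `UR` when reexcitation extinguished earlier. Reexcitation means some
  element activates at least twice after the stimulus plus a 50 ms latency
  (both windows configurable in `protocol_config()`).
* **Floor**: coupling intervals never go below 100 ms (runtime bound); the
  protocol also never delivers a stimulus earlier than 10 ms after the
  previous one.
* UR and R both count as "arrhythmic" in every tally and as the positive
  class downstream.

The state machine is deliberately decoupled from the solver: any function
`attempt(fixed_times, test_time, stage)` can stand behind it, which is how
the test suite verifies every S2/S3/S4 transition against hand-traced
scripts, independent of electrophysiology.

# Synthetic cohorts and the surrogate

`generate_population()` draws per-patient ischemic burden from a lognormal
distribution matched to mean 10.8% and SD 10.5% of myocardial volume
(truncated to [0.5, 45]); sheet dimensions vary ±15% patient-to-patient so
total myocardial volume is a genuine feature; the layer count grows with
burden over the 10–27 range. These defaults emulate the bookkeeping of a
30-patient post-infarct imaging cohort. What the generator does *not*
emulate: real infarct shapes (discs vs. irregular scars), 3D transmural
geometry of patient ventricles, inter-patient electrophysiological
variability, and MRI segmentation noise. Tests passing on these cohorts
therefore validate the pipeline's mechanics and directional claims, not
clinical performance.

Population-scale inducibility uses `surrogate_outcome_fn()`: the
probability of induction at a segment is logistic in global ischemic
burden and the paced segment's ischemic percentage — the two quantities the
mechanistic results identify as drivers — with the intercept calibrated
once (b0 = −3.4) so the baseline cohort's positive rate is ≈ 0.22.
Positives split 60/40 into sustained/unsustained. The full monodomain
protocol remains available per site (`run_vulnerability_protocol()`) and
is exercised in the tests (a healthy sheet is never inducible; a steep,
graded ischemic sheet supports reexcitation after a cross-field S2), but
evaluating 17 sites × hundreds of models × multiple coupling intervals is
cluster-scale, which is exactly the gap the surrogate fills.

# Classifier harness

Four features per (model, segment): segment myocardial volume, segment
ischemic percentage, total myocardial volume, total ischemic volume.
Labels: UR/R = 1, NR = 0. Seven models with fixed hyperparameters:
kNN (k = 5), RBF-SVM (C = 2), logistic regression, depth-3 decision tree,
gradient-boosted trees (pinned library defaults: 100 rounds, learning rate
0.3, depth 6), and 3-/4-hidden-layer perceptrons (32-17-8 and 32-17-8-8,
ReLU, two-unit softmax, RMSProp with zero momentum, exponential
learning-rate decay from 0.01, categorical cross-entropy, 25 epochs, batch
20). The perceptrons are trained by a small native backprop implementation
(`fit_mlp()`); batch normalization present in the original deep-learning
stack is omitted — at 4 input features and these depths it is not load
bearing, and the harness reports distributions over runs rather than
single fits.

Each experiment repeats `n_runs` times: shuffle, split 70/30, standardize,
fit, score. Standardization default is *per-split* (each split centred and
scaled by its own statistics) to mirror the reference experimental design this harness
reproduces; the conventional train-fit mode is one flag away
(`experiment_config(standardize = "train-fit")`) since per-split
standardization, while leakage-free, is statistically unusual. No class
rebalancing is applied (baseline positive rate ≈ 0.22, augmented ≈ 0.13);
stratified splitting is available as an option. Metrics: accuracy,
precision and sensitivity at threshold 0.5 per the printed formulas,
average precision as the recall-step-weighted precision mean, and AUC by
trapezoidal ROC integration — all cross-checked in tests against
brute-force enumeration and pair-counting oracles. `compare_populations()`
reports one-sided Welch t-tests (augmented accuracy greater) and one-sided
F-tests (augmented variance smaller), with two-sided values reported
alongside the one-sided ones.

# Problem sizes

The shipped experiments are sized for a single desktop CPU: synthetic
cohorts of 12–30 patients on 20 × 20 mm sheets at 0.25 mm spacing,
10 cohorts × 15 runs per arm for the augmentation comparison, strand
simulations of ≤ 3000 elements for CV physics, and one ~60 × 60 sheet
reentry demonstration. All were chosen as the smallest sizes at which the
directional claims are stable across seeds.

# Known limitations

* 2D sheets and voxelized shells instead of patient tetrahedral meshes;
  the protocol, grading and ML layers are representation-agnostic, which
  is the point, but absolute inducibility rates are not transferable.
* The surrogate inducibility model is a documented stand-in for
  population-scale programmed stimulation, calibrated to one scalar (the
  baseline positive rate); it inherits the logistic form, not the
  mechanism.
* Mixed-derivative diffusion terms are non-conservative; fiber fields with
  strong rotation should be treated with care.
* No bidomain, no mechanics, no Purkinje system, no scar evolution over
  time, no torso ECG.
* The restitution-slope scalar depends strongly on measurement protocol
  (see above); comparisons should fix the protocol, not the number.
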