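# reentryforge

An R package for studying post-infarct arrhythmia risk in silico, end to
end: it builds synthetic ventricular substrates with graded ischemic border
zones, probes them with a clinical-style programmed-stimulation protocol on
a built-in monodomain solver, expands small virtual cohorts by "peeling"
ischemic layers, and asks whether simple machine-learning classifiers can
predict per-segment inducibility from geometry alone — and whether
simulation-supported data augmentation makes them better.

It is aimed at computational electrophysiologists and ML-for-cardiology
researchers who want a desk-scale, fully scripted version of the
image-based modeling → simulation → classification pipeline, with every
stage testable in isolation.

## The science in brief

**Substrate.** A myocardial domain carries an ischemic subdomain divided
into L ∈ [10, 27] concentric layers by distance from the outer ischemic
surface. Severity grades inward: extracellular potassium rises linearly
7.5 → 10 mM from outermost to innermost layer; I_Na and I_CaL are reduced
20% (outer half of layers) or 30% (inner half); all ischemic tissue gets an
ATP-sensitive K⁺ current `I_KATP = g_KATP · f_ATP · (K_o/5.4)^0.24 ·
(V − E_K)` with f_ATP = 0.0049, and a 40% conductivity reduction.

**Electrophysiology.** The ten Tusscher–Panfilov (2006) human ventricular
myocyte model (Rush–Larsen gating, compiled core), in a monodomain
reaction–diffusion tissue `∂V/∂t = ∇·(D∇V) − I_ion` with anisotropic,
fiber-aligned conductivity. A steep-restitution parameter preset promotes
alternans and wavebreak.

**Vulnerability protocol.** Per AHA segment: five S1 beats at 350 ms cycle
length, then S2 coupled at 200 ms and decremented by 10 ms until reentry or
capture failure, then S3 and S4 at 250 ms likewise; 2000 ms observation per
premature beat; outcomes NR / UR / R (no, unsustained, sustained reentry).

**Augmentation.** Peeling the k outermost layers (k ∈ {1, 2, 5, 10})
relabels them healthy and re-grades the remainder from normal to fully
ischemic — each patient yields up to four additional, milder virtual
patients.

**Classification.** Four features per (model, segment): segment myocardial
volume, segment ischemic %, total myocardial volume, total ischemic
volume; label = inducible (UR/R) or not. Seven models (kNN k=5, RBF-SVM
C=2, logistic, depth-3 tree, gradient boosting, 3- and 4-hidden-layer
MLPs), 100×-repeatable 70/30 splits, accuracy/precision/sensitivity/AP/AUC,
and t-/F-tests comparing baseline vs augmented cohorts.

## Worked example

Generate a 12-patient synthetic cohort, peel it into a 60-model augmented
population, evaluate inducibility, and compare classifiers on both cohorts:

```r
library(reentryforge)

ex <- synthetic_risk_experiment(n_patients = 12, seed = 42)
ex$evaluation$summary
#> vulnerability: 163 of 1020 segments arrhythmic (ratio 0.160)
#>  peel n_patients mean_ischemia_pct ... pct_segments_reentry mean_reentries_per_model
#>     0         12            10.765 ...               22.059                    3.750
#>     1         12             9.042 ...               20.098                    3.417
#>     2         12             7.893 ...               19.608                    3.333
#>     5         12             5.035 ...               13.725                    2.333
#>    10         12             1.804 ...                4.412                    0.750
```

The baseline (peel 0) cohort is inducible at 22% of its 204 paced
segments, and inducibility falls monotonically as layers are peeled —
smaller injuries, fewer reentries. Now the classifier harness:

```r
cfg <- experiment_config(n_runs = 15, seed = 42)
mb <- run_experiment(ex$baseline,  cfg)   # 204 rows
ma <- run_experiment(ex$augmented, cfg)   # 1020 rows
ma
#> metrics_table: 15 runs x 7 models (0 failed)
#>     model   metric   mean      sd    max    min
#>  logistic accuracy 0.8839 0.01537 0.9085 0.8529
#>       svm accuracy 0.8824 0.01734 0.9052 0.8399
#>       nn3 accuracy 0.8802 0.01439 0.9052 0.8464
#>       nn4 accuracy 0.8800 0.01560 0.9020 0.8431
#>       knn accuracy 0.8743 0.01352 0.8922 0.8497
#>      tree accuracy 0.8678 0.02059 0.9020 0.8268
#>   xgboost accuracy 0.8678 0.01755 0.8922 0.8399

compare_populations(mb, ma)[, c("model", "mean_baseline",
                                "mean_augmented", "p_t_one_sided")]
#>     model mean_baseline mean_augmented p_t_one_sided
#>       knn         0.817          0.874      3.53e-06
#>       svm         0.831          0.882      6.54e-05
#>  logistic         0.848          0.884      7.33e-04
#>      tree         0.810          0.868      1.42e-04
#>   xgboost         0.802          0.868      1.68e-04
#>       nn3         0.826          0.880      4.95e-05
#>       nn4         0.814          0.880      1.46e-05
```

Every classifier gains accuracy (and loses run-to-run variance) when the
peel-augmented cohort is added — the augmentation effect the pipeline is
built to study. Cell-level building blocks are directly accessible too:

```r
restitution_slope(cell_params("steep"))$max_slope
#> [1] 2.736  # S1S2 maximum finite-difference slope of the steep preset

grade_layers(5)$K_o
#> [1] 7.500 8.125 8.750 9.375 10.000
```

A thin CLI over the same functions lives at `inst/cli/reentryforge.R`
(subcommands `geom`, `grade`, `augment`, `protocol`, `features`, `ml`,
`pipeline`, `fixtures`).

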