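---
title: "Classification-guided prediction and optimization of fermentation conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification-guided prediction and optimization of fermentation conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(fermopt)
library(dplyr)
```

## The problem

Liquid fermentation of the medicinal fungus *Phellinus* produces
flavonoids whose concentration (μg/ml of broth) depends on seven culture
factors: pH, temperature, initial medium volume, shaker rotation speed,
inoculum size, seed-culture age, and fermentation time. Campaigns in this
field are run as *single-factor series*: one factor sweeps a gradient
while the others sit at baseline values. That design is cheap and
interpretable, but it covers the seven-dimensional condition space only
along axis-aligned lines, and a regression fitted to the whole table is
dominated by the many deliberately poor conditions (pH 1, one hour of
fermentation, ...) that the campaign must include.

`fermopt` implements a four-stage pipeline for such data:

1. **Labelling.** A yield boundary converts records into high-yield
   (label 1) and low-yield (label 0) classes.
2. **Rebalancing.** SMOTE interpolation raises the minority high-yield
   class so classifiers are not dominated by the majority.
3. **Prediction.** A small feed-forward network regresses yield on the
   high-yield conditions only, where the response is informative.
4. **Optimization.** A real-coded genetic algorithm searches the
   condition box for the network's predicted maximum.

The packaged table (`phellinus_experiments()`) holds the 51 records of
the original campaign — six series covering pH 1–14, volume 40–140 ml,
inoculum 2–16%, temperature 25–40 °C, fermentation time 1–12, and seed
age 4–10 days — with yields from 20.9 to 2164.5 μg/ml.

## Labelling: two boundary strategies

`median_boundary()` splits the yields at their sample median (lower
median for even counts, so the threshold is always an observed yield).
It balances the classes perfectly but can swallow a whole series: every
seed-age record lies above the overall median, so under a median
boundary seed age ceases to be a decision factor for the classifier.
On the packaged table the computed median is 1088.1 μg/ml; a median is
a statistic of the records at hand, so subsetting the campaign moves
it.

`per_group_boundary()` instead requires every series to contain both
classes. A threshold `t` is feasible when each group has a record on
either side of it, i.e. `t` lies in the interval
(max of group minima, min of group maxima]. Among observed yields in
that interval the function picks the one balancing the class counts,
breaking ties toward the smallest. On the packaged table the feasible
interval is (1272.384, 1273.595] — delimited by the seed-age series
minimum below and the volume series maximum above — and any threshold in
it, such as the reproduction profile's 1273 μg/ml, gives 20 high-yield
and 31 low-yield records.

Labels use the `>=` convention (`assign_labels()`): a record exactly at
the boundary is high-yield. This is forced by the packaged data, where
1273.595 is high and 1272.384 is low at the 1273 boundary.

## SMOTE in gradient units

With 20 high against 31 low records the minority class is oversampled to
30 by SMOTE: each synthetic record lies uniformly at random on the
segment between a minority record and one of its `k = 5` nearest
minority neighbours. Distances are taken in **gradient units** — each
factor divided by its series increment (5 °C, 20 ml, 2% inoculum, ...) —
so one experimental step in any factor counts equally
(`to_gradient_units()`).

Two structural rules follow from the data's nature:

* Synthetic records carry **no yield** and are excluded from regression
  training by construction. Interpolated conditions were never run, so
  their yields are unknown; they only sharpen the classifier.
* The majority class passes through bitwise unchanged, and the
  augmented table appends synthetic rows after the originals, so any
  evaluation restricted to original records is unaffected.

`k = 5` is the canonical SMOTE neighbourhood; the target of 30 restores
near-balance (30 vs 31). Both are tunable (`smote_oversample()`).

## Classifiers and their evaluation protocol

Two classifiers are fitted over all seven factors in gradient units:

* `fit_logistic()` — maximum-likelihood logistic regression (via
  `stats::glm`), with internal standardization and constant features
  dropped with a warning (pH is constant in several subsets).
* `fit_bp_classifier()` — the same network family as the regressor with
  a logistic output unit and 0.5 cutoff.

Reports are 2×2 confusion matrices with per-class and overall percent
correct (`evaluate_classifier()`, `confusion_matrix()`). The
reproduction protocol fits on the full labelled set and scores the plain
models on the 51 original records and the SMOTE models on the 61-row
augmented set — the original study reports in-sample tables whose
marginals cover all records, and with 51 records a held-out protocol
would be too unstable to compare against. Accuracies must therefore be
read as descriptive of the fitted models, not as generalization
estimates.

## The yield regressor

The surrogate is a feed-forward network with layer layout (9, 9, 1) and
transfer functions tansig, logsig, tansig — two hidden layers of nine
units and a **tanh output unit** — trained by Levenberg–Marquardt on
sum-squared scaled error, stopping at an error target of 1e-5 or 1000
epochs. Damping starts at 1e-3, multiplies by 10 on a rejected step and
divides by 10 on an accepted one, so the recorded loss history is
non-increasing. All of this is authored in the package (no installed R
package provides this architecture/trainer combination); the Jacobian is
computed analytically layer by layer.

Two scaling choices matter:

* **Inputs** map to \[-1, 1\] by the *declared factor bounds*, not the
  sample range, so the optimizer may query the surrogate anywhere in the
  condition box.
* **Targets** map the training yields to \[-0.9, 0.9\]. The 0.9 gain
  keeps the extreme records off the tanh asymptotes (so the fit can
  actually reach its error target), and it bounds every prediction to
  about 5% beyond the observed training range. This is the package's
  central robustness device: a surrogate fitted to ~16 points with ~160
  parameters will interpolate, and with an unbounded output its
  extrapolations inside the box can reach several times the observed
  maximum, which both inflates holdout errors and hands the optimizer a
  fictitious optimum. The bounded output concedes that the data cannot
  support predictions far above what was measured.

pH is excluded from the regressor's inputs (dimension 6): every
high-yield record sits at pH 6, and a constant input carries no
information — this also matches the optimizer's six-gene chromosome.

Evaluation follows a repeated-holdout protocol
(`repeated_holdout()`): 7 independent seeded splits of the 20 high-yield
records into 16 training and 4 test records, a fresh network per split,
and the 28 per-record absolute and percentage errors concatenated
(`error_metrics()`, `aggregate_errors()`). On the packaged data this
yields mean percentage errors around 8–13% depending on the seed, i.e.
forecast accuracies (100 − mean percentage error) of roughly 87–92%.

## The genetic algorithm

`run_ga()` maximizes the trained surrogate over the factor box with a
real-coded elitist GA: population 300, six genes (pH pinned at 6 when
decoding), generation cap 1000, crossover rate 1, per-gene mutation rate
0.01, one elite, and a stall stop after 100 generations without
improvement — which is why runs converge within tens to hundreds of
generations despite the cap.

Operator choices (the method's description names only the rates):

* **Selection** is roulette-wheel on fitness shifted by the population
  minimum, with a flat landscape degenerating to uniform draws.
* **Crossover** is a blend (BLX-0.5): each child gene is drawn uniformly
  from the parents' interval extended by half its width on each side,
  clipped to the bounds. The classic whole-arithmetic blend (the
  `alpha = 0` special case) only ever contracts the population toward
  its mean; in corner-recovery probes it stalled about 25% short of a
  linear fitness' true corner, while BLX-0.5 reaches it exactly.
* **Mutation** resamples a gene uniformly within its bounds.

With one elite the best-so-far fitness is non-decreasing, and the
returned best always dominates the 300 random samples of the initial
population. A fixed seed reproduces the entire run bitwise.

## The synthetic generator and what passing tests mean

`response_model()` + `make_design()` + `simulate_yields()` generate
single-factor campaigns with a known truth: each free factor contributes
a unimodal effect curve (floor + Gaussian bump; sharp for pH-like
factors, broad for time-like ones), effects multiply, a global scale
sets the peak yield, and noise is multiplicative log-normal
(sdlog 0.1 by default, matching the ~10% error scale of the real
holdouts). `true_optimum()` returns the closed-form peak, which anchors
oracle tests: a dense grid search must agree with it, the regressor must
generalize on noiseless draws (held-out mean percentage error under
10%), and the full chain must rediscover the peak's *yield* within 10%.

The generator emulates the single-factor design structure and the
unimodal responses of the real campaign. It does **not** emulate factor
interactions (the product rule has none beyond multiplicativity),
heteroscedastic assay error, or the co-varying nuisance factors present
in two of the real series. Passing tests on synthetic data therefore
validate the pipeline's mechanics — labelling, rebalancing geometry,
trainer convergence, optimizer behaviour — not the biological fidelity
of any fitted surrogate.

## Known limitations

* **The optimum's location is not identifiable from this design.** The
  regressor trains on high-yield records only, which lie on axis-aligned
  series; the interior of the box is unconstrained, so the bounded
  surrogate forms a broad near-ceiling plateau and the GA's argmax
  wanders on it. In zero-noise synthetic recovery runs the chain
  reliably recovers the peak *yield* within a few percent while placing
  only some of the six conditions within one gradient step of the true
  peak. The package asserts both halves of that recovery property in its
  acceptance tests and the location half fails by design of the method,
  not of the implementation; treat optimized *conditions* as candidates
  for confirmation experiments, not as estimates.
* In-sample classifier accuracies (above) are descriptive, not
  generalization estimates.
* The per-group boundary requires overlapping series; campaigns whose
  series do not overlap in yield have no feasible threshold, and the
  function says which groups block it.
* The fermentation-time unit is stored as printed (1–12) without
  conversion; the campaign's own records are internally consistent.

## Problem sizes used in tests

Test and acceptance runs use the study's own sizes: the 51-record table,
61 rows after SMOTE, 7×(16/4) holdouts, networks of 163 parameters, and
GA populations of 300 for up to 1000 generations (stall 100). Synthetic
checks use 6-series designs of 5–9 steps per factor. A full
`run_study()` takes a few seconds on one core.
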