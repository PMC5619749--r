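# fermopt

Surrogate-assisted optimization of liquid-fermentation culture
conditions from single-factor experiment campaigns, built around
flavonoid production by the medicinal fungus *Phellinus*.

Such campaigns vary one culture factor at a time — pH, temperature,
initial medium volume, rotation speed, inoculum size, seed age,
fermentation time — and record the flavonoid yield (μg/ml). Most
records are deliberately poor conditions, so a regression over the whole
table learns little about the productive region. `fermopt` implements
the classification-first pipeline for this situation:

1. **Label** records high/low-yield at a boundary *t*: either the yield
   median, or the per-group balanced boundary — the threshold inside
   (max<sub>g</sub> min<sub>i∈g</sub> y<sub>i</sub>,
   min<sub>g</sub> max<sub>i∈g</sub> y<sub>i</sub>] that keeps every
   single-factor series split while minimizing |n₁ − n₀|.
2. **Rebalance** the minority high-yield class with SMOTE: synthetic
   records x<sub>m</sub> = x + u·(x<sub>n</sub> − x), u ~ U[0, 1), with
   neighbours found by Euclidean distance in *gradient units* (each
   factor divided by its series increment). Synthetic records carry no
   yield and never enter regression training.
3. **Classify** with logistic regression and a feed-forward network;
   report confusion matrices with per-class percent correct.
4. **Predict** yield on the high-yield records with a 6–9–9–1 network
   (tansig, logsig, tansig transfer functions; pH excluded as constant)
   trained by Levenberg–Marquardt to a 1e-5 scaled sum-squared-error
   target, inputs scaled to [−1, 1] by the factor bounds and targets to
   [−0.9, 0.9]. Errors are z = |x − y| and z/x per held-out record over
   a repeated 16-train/4-test protocol (7 repeats).
5. **Optimize** the trained surrogate with a real-coded elitist GA
   (population 300, 6 genes, crossover rate 1, mutation rate 0.01,
   generation cap 1000 with a 100-generation stall stop).

The 51 records of the original campaign ship with the package
(`phellinus_experiments()`), as does a synthetic single-factor
generator with a closed-form optimum (`response_model()`,
`make_design()`, `simulate_yields()`, `true_optimum()`) used for
oracle tests.

## Worked example

```r
library(fermopt)
library(dplyr)

tbl <- phellinus_experiments()

# balanced per-group boundary: feasible interval and chosen threshold
per_group_boundary(tbl)
#>   threshold interval_lower interval_upper n_high n_low
#> 1     1274.          1272.          1274.     20    31

# the reproduction profile uses the 1273 boundary inside that interval
labelled <- assign_labels(tbl, 1273)
class_counts(labelled)
#>   n_low n_high imbalance
#> 1    31     20      1.55

# SMOTE to 30 high-yield records, then a logistic report
augmented <- smote_oversample(labelled, k = 5, target = 30, seed = 1)
tidy(evaluate_classifier(fit_logistic(augmented), augmented))
#>   truth predicted_0 predicted_1 correct_pct
#> 1 0              25           6        80.6
#> 2 1              10          20        66.7
#> 3 total          NA          NA        73.8

# repeated 16/4 holdout of the yield regressor over the 20 high records
high <- filter(labelled, label == 1)
aggregate_errors(repeated_holdout(high, seed = 1))
#>       n mean_error mean_pct_error forecast_accuracy
#> 1    28       144.           8.89              91.1

# train-then-optimize: the GA's best condition and predicted yield
net <- train_network(high, seed = 1)
tidy(run_ga(net, ga_params(), seed = 1))
#>      ph temperature_C initial_volume_ml rotation_speed_rpm inoculum_pct
#> 1     6            25               140                150         9.39
#>   seed_age_d fermentation_time predicted_yield iterations
#> 1      10.00                 1           2214.        114
```

Reading the numbers: the campaign's 51 records split 20 high / 31 low at
the 1273 μg/ml boundary; the rebalanced logistic model scores 73.8%
overall; the regressor's mean held-out percentage error is 8.9%, i.e. a
forecast accuracy of 91.1%; and one train-then-GA run predicts a best
achievable yield of about 2214 μg/ml — a few percent above the best
observed experiment (2164.5 μg/ml). The optimized *conditions* lie on
the surrogate's high plateau and should be treated as candidates for
confirmation runs, not point estimates (see the vignette's limitations
section). `run_study(seed = 1)` chains all stages, and each result type
has `tidy()`/`glance()`/`autoplot()` methods.

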