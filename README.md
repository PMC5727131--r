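# cgmboost

Clinicians routinely need to distinguish type 1 from type 2 diabetes, but the
standard laboratory tests (C-peptide, islet autoantibodies, insulin release)
are incomplete and sometimes ambiguous. Continuous glucose monitoring (CGM)
records a patient's glucose concentration every 5 minutes — 288 samples a
day — and the *shape* of that day-curve carries type information: type 1
patients tend to show larger, sharper glycemic excursions and more
hypoglycemia, type 2 patients a higher but flatter profile.

`cgmboost` implements a two-stage classification indicator on top of CGM
day-curves, for biostatisticians and ML researchers working with glycemic
time series:

1. **Feature extraction** — 17 glycemic-variability features per patient,
   computed per day and averaged: the whole-day mean and six pre-/post-meal
   window means (x̄ = (1/n) Σ xᵢ); SDBG, the population standard deviation
   √((1/n) Σ (xᵢ − x̄)²); LAGE = x_max − x_min; MODD, the mean absolute
   difference between time-matched samples of consecutive days
   ((1/287) Σᵢ₌₁²⁸⁸ |v₁(i) − v₂(i)|, as printed); the excess area AUC beyond a
   configurable target range [lower, μ]; MAGE, the mean amplitude of
   glycemic excursions exceeding one SDBG, computed from local extrema; the
   excursion counts TH/TL (peaks above μ, troughs below the lower limit);
   and the time percentages HL/LL/WL above/below/within the range. The upper
   threshold μ is a tuning parameter, typically swept over 7–11 mmol/L.

2. **Boosted classification** — binary type 1 (+1) vs type 2 (−1)
   classification of the 17-feature vectors by four from-scratch AdaBoost
   variants over decision stumps / per-feature block learners:

   * *discrete*: weighted-error-minimizing stumps, αₜ = ½ ln((1−εₜ)/εₜ),
     weights Dₜ₊₁ ∝ Dₜ exp(−αₜ yᵢ hₜ(gᵢ)), H(g) = sign(Σ αₜ hₜ(g));
   * *Real*: per-feature partition into blocks G₁…Gₙ, block output
     ½ log(p₊ʲ/p₋ʲ) with Schapire–Singer smoothing, feature chosen to
     minimize z = 2 Σⱼ √(p₊ʲ p₋ʲ);
   * *Gentle*: regression stumps fit by weighted least squares of y on g;
   * *Modest*: block outputs damped by the inverted weight distribution,
     fʲ = p₊ʲ(1 − p̄₊ʲ) − p₋ʲ(1 − p̄₋ʲ).

Around these it provides the evaluation protocols used to study such an
indicator — a seeded 300:750-ratio hold-out split, stratified 5-fold
cross-validation, accuracy and Matthews correlation coefficient, per-iteration
test-error curves, and a (variant × μ) threshold sweep — plus a seeded
simulator of labeled CGM cohorts, CSV I/O for traces and feature tables, JSON
model serialization, ggplot2 `autoplot()` methods and broom-style
`tidy()`/`glance()` methods, and a small command-line pipeline.

## Worked example

```r
library(cgmboost)

# a labeled synthetic cohort: 100 type 1 + 100 type 2 patients, 2 days each
cfg     <- simulation_config(n_per_class = c(t1d = 100, t2d = 100), seed = 42)
cohort  <- simulate_cohort(cfg)

# stage 1: the 17 features at upper threshold mu = 7 mmol/L
features <- extract_feature_table(cohort, threshold_config(upper = 7))
features[1:3, c("patient_id", "mean_day", "sdbg", "lage", "mage", "hl", "label")]
#> # A tibble: 3 × 7
#>   patient_id mean_day  sdbg  lage  mage    hl label
#>   <chr>         <dbl> <dbl> <dbl> <dbl> <dbl> <int>
#> 1 T1D_0001       7.93  1.48  6.87     0  69.8     1
#> 2 T1D_0002       7.38  1.59  6.51     0  40.1     1
#> 3 T1D_0003       8.10  1.65  7.38     0  77.1     1

# stage 2: Modest AdaBoost, T = 100 rounds, 2/7 train : 5/7 test split
eval7 <- holdout_protocol(features, variant = "modest", n_rounds = 100, seed = 42)
glance(eval7)
#> # A tibble: 1 × 6
#>   variant error_rate   acc   mcc n_train n_test
#>   <chr>        <dbl> <dbl> <dbl>   <dbl>  <dbl>
#> 1 modest      0.0350 0.965 0.932      57    143

kfold_cv(features, variant = "modest", n_rounds = 100, k = 5, seed = 42)
#> <cv_eval> modest, 5 folds: per-fold error 0.000 0.000 0.000 0.025 0.000; mean 0.0050
```

The hold-out row reads: with 57 training and 143 test patients, the Modest
ensemble mislabels 3.5 % of held-out patients (accuracy 0.965); the MCC of
0.93 indicates the errors are balanced across both types. Each patient row
shows their averaged day-curve features — e.g. `T1D_0001` spends 69.8 % of
the day above 7 mmol/L (`hl`). (`mage` is 0 here because measurement noise
breaks large swings into sub-SD steps between consecutive extrema; see the
methods vignette.)

`threshold_sweep(cohort)` repeats extraction and evaluation over
μ ∈ {7, 8, 9, 10, 11} for all four variants and `autoplot()` draws the
error-vs-iteration curves per threshold. A command-line version of the
pipeline lives in `inst/cli/cgmboost.R`
(`simulate | extract | train-eval | sweep`).

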