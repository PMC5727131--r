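---
title: "Glycemic features and boosted diabetes-type classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycemic features and boosted diabetes-type classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cgmboost` turns continuous glucose monitoring (CGM) day-curves into a
scalar diabetes-type indicator in two stages: 17 glycemic-variability
features per patient, then a boosted binary classifier over those features.
This vignette records the model, the tunable parameters, and the design
decisions taken where the underlying definitions are ambiguous or silent —
the things a maintainer or a careful user needs to know before trusting a
number.

## The data model

A `glucose_trace` is one patient's record: glucose in mmol/L on an exact
5-minute grid, 288 samples per day, at least two whole days (the inter-day
feature MODD needs a day pair). The grid is assumed complete; readers of raw
CSV either reject a day with missing samples (default) or, when
`impute = TRUE`, fill interior gap runs of at most 3 samples (15 min) by
linear interpolation. A trailing partial day is dropped with a warning.
These rules exist because every feature below assumes a complete grid;
imputation beyond a few samples would invent structure.

## Stage 1 — the 17 features

For a day $x_1,\dots,x_{288}$ and a target range $[\ell, \mu]$:

* **Seven period means.** The whole-day mean $\bar x = \frac1n\sum x_i$ and
  the means over six meal windows: $[m - 30\,\text{min}, m)$ before and
  $(m, m + 120\,\text{min}]$ after each of breakfast, lunch and dinner.
  A sample belongs to a window when its *slot midpoint* lies inside it, so
  membership is unambiguous on the discrete grid. Meal clock times are not
  part of the raw data; the defaults 07:30 / 12:00 / 18:00 are ordinary
  hospital meal times and are configurable (`meal_schedule()`). Windows must
  not overlap.
* **SDBG** — the *population* standard deviation
  $\sqrt{\frac1n\sum (x_i-\bar x)^2}$, divisor $n = 288$, deliberately not
  the $n-1$ sample form: the day is treated as the complete object of
  interest, and the definition is implemented exactly as written.
* **LAGE** $= x_{\max} - x_{\min}$.
* **MODD** — for consecutive days $v_1, v_2$:
  $\frac{1}{287}\sum_{i=1}^{288} |v_1(i)-v_2(i)|$. The 288-term sum with
  divisor 287 is internally inconsistent (a mean of 288 terms would divide
  by 288), but it is the printed definition and is implemented as printed;
  `modd_denominator = 288` is available as an escape hatch. At CGM noise
  levels the difference is a factor 288/287 ≈ 0.35 %.
* **Excess AUC** — the area of the curve above $\mu$ plus the area below
  $\ell$, in mmol/L·h. Quadrature: trapezoidal integration on the
  slot-midpoint grid extended to the day boundaries by constant
  continuation. This makes the integral span the full 24 h — a curve
  constantly 1 mmol/L above $\mu$ scores exactly 24 mmol/L·h — and is
  algebraically identical to a 5-minute rectangle rule on the slot values.
  A trapezoid over the 288 sample instants alone would span only
  287/12 h and systematically shrink every area by ~0.35 %.
* **MAGE** — mean amplitude of glycemic excursions, by the four-step
  extrema procedure: (1) collect all interior local extrema; (2) find the
  first extreme point whose distance to *both* adjacent extrema exceeds the
  day's SDBG; (3) collect the amplitudes $|ep_i - ep_{i+1}|$ of consecutive
  extrema pairs, keeping those above the SDBG, each pair once; (4) average
  the kept amplitudes; 0 when step 1 or 2 finds nothing. Two points needed
  decisions:
  * *Plateaus.* Strict sign-change extrema are undefined on runs of equal
    values, so each run is collapsed to its midpoint sample before extrema
    detection. This removes all tie-breaking.
  * *Direction of accumulation.* Step 3's walking direction is stated
    ambiguously in the literature; accumulating every consecutive
    valid-pair amplitude exactly once is direction-independent and is what
    the package does. The choice is isolated in `mage()`.
  * *A consequence worth knowing:* on noise-dominated curves, consecutive
    extrema are mostly adjacent noise wiggles whose amplitudes sit far
    below the SDBG, so MAGE frequently returns 0 even when the day contains
    visually large excursions. That is the faithful behaviour of the
    consecutive-extrema formulation; practical MAGE variants often
    pre-smooth the signal, which is out of scope here.
* **TH / TL** — counts of local maxima above $\mu$ and local minima below
  $\ell$ (episode-peak reading of "extreme points over the threshold
  line"). An alternative reading — the number of maximal runs of samples
  beyond the threshold — is available as `th_tl_mode = "crossings"`,
  default off.
* **HL / LL / WL** — percent of samples above $\mu$, below $\ell$, and the
  remainder; they sum to 100 by construction.

The lower threshold $\ell$ defaults to 3.9 mmol/L, the standard
hypoglycemia cut-off; only the upper threshold $\mu$ is usually swept
(7–11 mmol/L, the glucose target-range ceilings of interest).

**Multi-day aggregation.** Per-day features are averaged across days; MODD
is computed on each consecutive day pair and averaged. How a multi-day
record collapses to one feature row is a design choice; averaging keeps
every feature in per-day units.

## Stage 2 — boosting variants

Training data are $m$ labeled feature vectors $g_i \in \mathbb{R}^{17}$,
$y_i \in \{+1,-1\}$ (+1 = type 1), weights initialized $D_1(i) = 1/m$ and
renormalized to sum to 1 after every round. All four variants are
implemented from first principles; none wraps an external learner.

* **Discrete AdaBoost.** Each round fits the weighted-error-minimizing
  decision stump, $\varepsilon_t = \sum_i D_t(i)[y_i \ne h_t(g_i)]$,
  $\alpha_t = \tfrac12\ln((1-\varepsilon_t)/\varepsilon_t)$,
  $D_{t+1} \propto D_t e^{-\alpha_t y_i h_t(g_i)}$;
  $H(g) = \operatorname{sign}(\sum_t \alpha_t h_t(g))$.
* **Real AdaBoost.** Each feature's range is partitioned once into
  `n_bins = 8` equal-frequency blocks (quantile edges from the training
  data). Per round and feature the block masses
  $p_\pm^j = \sum_{g_i \in G_j,\, y_i = \pm 1} D(i)$ give outputs
  $\tfrac12\log(p_+^j/p_-^j)$ and the selection criterion
  $z = 2\sum_j \sqrt{p_+^j p_-^j}$ (minimized); the weight update is
  $D \propto D e^{-y h(g)}$.
* **Gentle AdaBoost.** A regression stump fit by weighted least squares:
  outputs are the weighted means of $y$ on each side of the cut, the cut
  minimizing weighted squared error. Its exponential loss is
  provably non-increasing, which the tests assert numerically.
* **Modest AdaBoost.** Alongside $D$, the inverted distribution
  $\bar D \propto (1-D)$ is maintained; block outputs
  $f^j = p_+^j(1-\bar p_+^j) - p_-^j(1-\bar p_-^j)$ are bounded in
  $[-1, 1]$ and damp confident regions; the feature maximizing the
  weighted margin gain $\sum_i D(i) y_i f(g_i)$ is chosen.

Numerical and degeneracy decisions, all deterministic:

* Stump thresholds are midpoints between consecutive sorted unique feature
  values, searched exhaustively over all 17 features; ties in the round
  objective break toward the lowest feature index, then lowest threshold.
* $\varepsilon_t = 0$ (perfect stump): the weight formula uses
  $\varepsilon \leftarrow \max(\varepsilon, 10^{-10})$ and training stops
  after that round — further rounds would merely rescale the same vote.
* $\varepsilon_t = 0.5$ exactly: no stump beats chance ($\alpha = 0$,
  weights frozen); training stops *before* adding the useless learner.
  Polarity flipping makes $\varepsilon_t > 0.5$ unreachable. A useful
  boundary case: on four XOR-placed points at exact corners *every*
  univariate stump sits at precisely 0.5 — no boosting variant over
  univariate weak learners can make progress there.
* Real/Modest probabilities are smoothed as
  $p \leftarrow p + \varepsilon_s$ in the log-odds ratio with
  $\varepsilon_s = 1/(4m)$, preventing infinite outputs; an empty block
  outputs exactly 0. A Modest round whose best learner has non-positive
  margin gain stops training.
* $\operatorname{sign}(0) \to +1$, documented, so predictions are
  deterministic.
* `n_rounds` defaults to T = 100.

Models serialize to versioned JSON at full numeric precision; a restored
model reproduces the original predictions (scores to ~1e-15 relative).

## Evaluation protocols

* `confusion_matrix()` with positive class +1 (type 1);
  $ACC = (TP+TN)/(P+N)$; MCC with the standard 0-on-zero-denominator
  convention (a constant prediction carries no correlation).
* `holdout_protocol()`: a seeded shuffle, `round(train_ratio * n)` training
  rows, the rest test. The default ratio 2/7 reproduces a 300:750 split at
  n = 1050 and scales proportionally elsewhere.
* `kfold_cv()`: *stratified* k-fold (k = 5 default). Plain random folds can
  produce single-class training folds on small cohorts; stratification
  removes that failure mode while keeping fold sizes within one sample.
* `threshold_sweep()`: for each $\mu$ the features are re-extracted and
  every variant is evaluated on the *same* seeded split, yielding a
  (variant × μ) grid of error/ACC/MCC and per-round test-error curves.

## The cohort simulator

Real labeled CGM cohorts of useful size are not publicly available, so
`simulate_cohort()` generates one: per day, a patient-specific baseline +
a slow circadian sinusoid + three meal-locked Gaussian excursions (peak
~75 min post meal) + optional hypoglycemic dips and brief hyperglycemic
spikes (Poisson-placed) + white measurement noise, clipped to the sensor
range [2, 25] mmol/L. A master seed derives an independent substream per
patient, so cohorts are reproducible and removing one patient leaves the
others byte-identical.

Two presets encode the study conditions used by the tests:

* **`default`** — textbook phenotype contrast: type 1 at baseline
  7.0 mmol/L with 4.5 mmol/L meal excursions and 0.5 hypo dips/day; type 2
  at 8.5 mmol/L with blunted 2.0 mmol/L excursions and 0.05 dips/day;
  between-patient baseline SD 0.5, noise SD 0.3. This cohort is strongly
  learnable by construction; `zero_contrast()` averages every class-paired
  parameter to produce an exchangeable null cohort on which held-out error
  must sit at chance.
* **`threshold_structured`** — both classes share the baseline
  (4.7 mmol/L), meal excursions (1.0 mmol/L) and a per-patient "glycemic
  instability" oscillation (amplitude uniform 0.4–1.5 mmol/L, period 3 h)
  drawn identically for both classes; the *only* class contrast is the
  rate of brief spikes into the 7–9 mmol/L band (3/day vs 0.3/day, height
  ≈ 3.2 mmol/L over baseline). The shared oscillation dominates the
  dispersion features (SDBG, LAGE, MAGE) for both classes, so the class
  signal concentrates in the threshold-dependent features (TH, HL, AUC) at
  μ = 7–8 and vanishes from them at μ = 10–11, where neither class
  crosses the threshold. On such cohorts the sweep shows lower error in
  the 7–8 band than in the 10–11 band for every variant — the qualitative
  pattern the threshold sweep is designed to expose.

What the simulator does **not** emulate: sensor dropout and compression
artifacts, meal-time variation between patients, insulin or medication
dynamics, age and demographic structure, and the day-to-day autocorrelation
of real physiology beyond the shared baseline. Passing tests on simulated
cohorts therefore demonstrate the *pipeline's* correctness and the
*relative* behaviour of the variants, not clinical accuracy on hospital
data.

## Problem sizes used by the checks

The package's own verification uses: feature oracles on ~120 random
day-curves and 1000 random MAGE traces; boosting guarantees on 40–60-sample
tables; end-to-end label recovery on 525+525-patient cohorts (2 days each,
T = 100, μ = 7, 10 seeds, with matched null cohorts); and the sweep pattern
on ten 150+150-patient structured cohorts across all four variants and
μ ∈ {7,…,11}. These sizes give stable Monte-Carlo estimates while keeping a
full run in the minutes range on one CPU.

## Known limitations

* MAGE inherits the consecutive-extrema formulation's collapse toward 0 on
  noise-dominated curves (see above).
* TH/TL peak counting and MAGE depend on exact-equality plateau collapse;
  on continuous-valued noisy data plateaus are rare, but quantized exports
  (e.g. values rounded to 0.1 mmol/L) will produce them, and the two TH/TL
  modes can then differ noticeably.
* The 300:750 protocol trains on only 2/7 of the data; with small cohorts
  the training set becomes the binding constraint on accuracy.
* Real hospital validation data are not bundled; every quantitative result
  in the test suite and acceptance script is computed on the simulator
  described above.
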