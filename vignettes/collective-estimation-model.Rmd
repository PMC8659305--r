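---
title: "Modelling social information use in collective estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling social information use in collective estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdshift)
```

## The problem

When people estimate large quantities — the number of dots on a sheet, the
population of a city — they systematically underestimate, and the bias
grows with the magnitude of the quantity.  On the log scale the effect is
remarkably regular: the median log estimate `m` of a group is close to
`gamma * log10(T)` with a slope `gamma` around 0.9, where `T` is the true
value.  A slope below 1 *is* the underestimation bias.

crowdshift studies what happens when members of a group of size 12 revise
a personal estimate after seeing `tau` estimates from other members, and
whether choosing *which* estimates to share can cancel the bias.  Three
sharing rules are implemented:

* **random** — `tau` estimates from randomly chosen other members;
* **median** — the `tau` estimates (excluding one's own) closest in log
  to the group median `m`, which prunes extreme values;
* **shifted median** — the `tau` estimates closest to `m' = m / gamma`.
  Since `m` underestimates `log10(T)` with slope `gamma`, `m'`
  approximates the log truth without anyone knowing the truth: the rule
  only uses prior domain knowledge of the bias slope.

All analysis happens in deviation coordinates `X = log10(E / T)`, which
make questions of very different magnitude comparable; `X = 0` is a
perfect estimate, and the group median of `X` sits near
`(gamma - 1) * log10(T) < 0`.

## The behavioral model

Agents are assumed to perceive two summaries of the estimates they
receive: the mean `M` of the shared log estimates (equivalently the log
of the geometric mean of the raw estimates) and their mean absolute
deviation `sigma`.  Three behavioral regularities drive the model:

* **distance effect** — the mean weight given to the social information
  grows linearly with the distance `|D - D0|`, where `D = M - X_p`;
* **asymmetry effect** — the cusp bottom `D0` is negative and the right
  slope exceeds the left one, so information *above* one's estimate is
  weighted more than information below it;
* **similarity effect** — the weight decreases linearly with the
  dispersion `sigma` of what is received: disparate advice is followed
  less.

These combine into the linear cusp
`<S>(D, sigma, tau) = alpha + beta_pm |D - D0| + beta' sigma`,
with `beta_minus` left of `D0`, `beta_plus` right of it, and the
similarity term only when `tau > 1` (a single estimate has no
dispersion).  The realized sensitivity is drawn from a
**spike-and-Gaussian** law: with probability `P0` the agent keeps its
estimate exactly (`S = 0`); otherwise `S ~ N(m_g, sigma_g)`.  Writing
`P_g = 1 - P0`, consistency of the mean forces `<S> = P_g m_g`, so the
simulator computes `P_g = <S> / m_g` pointwise.  `m_g` and `sigma_g` are
constants at `tau = 1` and linear functions of `sigma` at `tau > 1`
(`m_g` decreasing, `sigma_g` increasing).  Finally the agent updates

```
X_s = (1 - S) X_p + S M
```

a weighted mean that may extrapolate when `S` falls outside `[0, 1]`.
Two reduced variants isolate single mechanisms: `no_asymmetry`
(`D0 = 0`, common slope) and `no_similarity` (`beta' = 0`, flat `m_g`
and `sigma_g`).  Simulating them alongside the full model shows which
empirical signatures each mechanism carries: the asymmetry produces the
improvement in collective accuracy (second estimates are pulled upward,
against the bias), the similarity effect the boost of social information
use in the median-based treatments, and the herding range
`0 < <S> < 1` the narrowing of the estimate distribution that improves
individual accuracy everywhere.

## What the generator emulates

`generator_config()` reproduces the structure of the emulated
experiments: 18 groups of 12 subjects, 36 questions, and the 18
conditions (3 treatments x `tau` in 1, 3, 5, 7, 9, 11).  A deterministic
Latin-square rotation assigns conditions to (group, question) cells so
that each group meets each condition exactly twice and each question
meets each condition in exactly one group — hence exactly
`12 * 36 = 432` records per condition.

Per question, log estimates follow a Laplace distribution: its center is
`gamma_bias * log_true` plus Gaussian question-level noise, its width is
the mean absolute deviation of log estimates.  Raw estimates must exceed
1, so sampling is truncated below at `X = -log_true` using the exact
inverse-CDF of the conditioned Laplace (a shifted-exponential draw when
the truncation point reaches the center; no rejection loop, no tail
overflow).

Defaults, chosen once: `gamma_bias = 0.9` (the bias slope the shifted
median compensates), `log_true_range = [2, 7]` (moderately large to very
large quantities), `width_range = [0.3, 0.6]` and
`question_noise_sd = 0.3` (plausible spreads for heterogeneous general
knowledge and numerosity items; real per-question dispersions are not
published, so these are stand-ins).  What the generator does **not**
emulate: subject-level heterogeneity in the keep-probability `P0`,
question semantics (categories are carried as tags only), integer
rounding of raw answers, and any dependence between a subject's answers
across questions.  Passing tests therefore demonstrate internal
consistency of the estimation machinery under the model, not that the
model is true of any particular population.

## Numerical choices

* **Base-10 logs** throughout; estimates are "orders of magnitude"
  quantities.
* **Selection ties** (equal distance to the reference) are broken toward
  the smaller log estimate, then the smaller subject index; duplicate
  values are distinct subject-attached items.  The group median includes
  the focal subject; only the *shared* set excludes them.
* **`P_g` clamping**: the linear cusp can push `<S> / m_g` outside
  `[0, 1]` at extreme `D`; the probability is clamped and every clamp
  counted (reported in the simulation's `guards` attribute and the
  pipeline manifest).  Likewise `m_g` and `sigma_g` are floored at
  `1e-3` where their linear laws would cross zero.
* **Sensitivity recovery**: `S = (X_s - X_p) / (M - X_p)` explodes when
  `M` is close to `X_p` without reflecting a real adjustment, so S-based
  analyses clip to `[-1.05, 2.05]` and records with `M = X_p` exactly
  are excluded (flagged, never an exception).  Exact zeros are
  identified by provenance — the second estimate equals the first — not
  by a numeric tolerance.
* **Mixture fit**: the non-zero part of the S histogram (bin width 0.1
  on the clipping interval, density-normalized by the total count) is
  fitted by `nls` with the constraint `P_g = mean(S) / m_g` substituted,
  so `m_g` and `sigma_g` are the only free parameters; a bounded
  `optim` fallback covers non-convergence.  An `S = 1` peak
  (exact adoption of the geometric mean) is not modelled: with several
  shared estimates a second estimate essentially never lands exactly on
  their mean.
* **Cusp fit**: with `D0` fixed, the model is linear in
  `(alpha, beta_minus, beta_plus, beta')` and solved in closed form from
  the design matrix, unweighted over individual records with `D` in
  `[-2.5, 2.5]` (every answer counts equally); `beta'` is dropped at
  `tau = 1`.
* **Locating `D0`**: two estimators are provided.  `fit_D0()` fits a
  V-function to the moving-bin curve (overlapping bins of size 1,
  centers stepping by 0.1), the display-level procedure; but box
  smoothing rounds an asymmetric cusp and drags the apparent bottom
  toward the shallow-slope side by up to ~0.2, so the fitting pipeline
  uses `fit_D0_profile()`: a grid search over `D0` of the record-level
  closed-form least squares, refined parabolically.  Profiling is
  unbiased because no smoothing intervenes.  The search interval is
  `[-1.2, 0.2]`, widened to `[-1.2, 0.6]` for the three conditions with
  a shallow empirical bottom.
* **Bootstrap**: the sampling unit is the question (all records of a
  drawn question enter together), bars are asymmetric at 68.3% coverage
  by analogy with one standard deviation, and every comparison is
  paired — the significance level `p0` of a claim is the fraction of
  replicates contradicting it on the *same* resampled question sets,
  never a comparison of overlapping bars.  When no contradicting
  replicate occurs, `p0` is reported as 0 with upper bound `1 / n_boot`.
* **`tau = 1` keep-probability**: the model computes `P_g` from the cusp
  mean at `tau = 1` as well (D-dependent), using the constant
  `m_g`/`sigma_g` of the single-estimate block — the same mechanism as
  `tau > 1` without the similarity term.
* **Improvement averaging**: before/after accuracies are averaged over
  the `tau` levels with equal weights; the balanced design gives every
  level the same record count, so count-weighting would coincide.

## Problem sizes

Simulation-heavy checks are run at sizes chosen to keep Monte-Carlo
error well below the tolerances they are compared against: parameter
recovery uses 150 runs of the full design (about 65,000 sensitivity
records per condition, making the statistical error of every recovered
parameter a few thousandths), mechanism signatures use 10–30 runs, and
accuracy bootstraps use 1,000 replicates.  Averages over many more runs
change none of the reported digits that matter at those tolerances.

## Known limitations

* The recalibration baseline (`X' = (X + log10 T) / gamma - log10 T`,
  i.e. dividing log estimates by the bias slope) always removes the
  median bias but stretches the dispersion by `1 / gamma`.  Whether it
  *degrades* individual accuracy therefore depends on the ratio of bias
  to dispersion: under this generator's defaults the pooled bias
  (~0.5 orders of magnitude) outweighs the stretching and recalibration
  improves individual accuracy too, whereas in regimes with smaller
  bias relative to spread it degrades it.  The package reports both
  accuracies and leaves the interpretation to the regime at hand.
* Fitted `m_g`/`sigma_g` dispersion laws are poorly identified from the
  random treatment alone, whose mean dispersion barely varies with
  `tau`; slopes should be read from the median-based treatments.
* The model has exactly one revision round; iterated influence is out
  of scope.
* Drawn sensitivities are not clipped inside the simulator — clipping
  is an analysis-side filter — so simulated and reanalyzed data pass
  through the identical pipeline as experimental records would.
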