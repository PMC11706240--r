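---
title: "Benchmarking the speed-accuracy trade-off: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking the speed-accuracy trade-off: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satbench)
```

## The scientific problem

When people categorize objects under time pressure, their accuracy rises
smoothly with the time they are allowed: the speed-accuracy trade-off
(SAT).  Dynamic neural networks — models with early exits, recurrent
cycles, or cascaded outputs — produce one prediction per computational
budget, giving them an analog of reaction time.  `satbench` implements the
analysis pipeline for comparing the two: trial-level quality control for
the timed "beep paradigm", SAT-curve construction and normalization, a
timestep-to-reaction-time mapping, and three comparison metrics (curve-fit
RMSE, category-wise rank correlation, and a mean-curvature steepness
statistic), plus a synthetic-data generator so the whole pipeline runs
without a behavioral dataset or trained networks.

## The experimental design being analysed

A session of the beep paradigm consists of an untimed training block of 50
trials followed by five timed blocks of 210 trials.  Each timed block has
one beep latency (500, 900, 1,100, 1,300 or 1,500 ms after stimulus
onset); observers must click one of 16 category buttons at the beep, and a
200 ms grace period after the beep still counts as a response.  Block
order is ascending or descending with equal probability.  The analysis
rules encoded in the package are:

* **Observer exclusion.**  An observer whose timed responses fall outside
  a ±100 ms window around the beep on at least 50% of trials is excluded
  (`filter_observers()`; missing responses count as outside; the boundary
  is inclusive).
* **Warm-up discard.**  The first 10 trials of every timed block are
  dropped (`discard_warmup()`), leaving 200 analysed trials per block.
* **Missing responses.**  Trials with no response within the beep latency
  plus grace are either imputed with a uniformly random category — the
  default, which biases measured accuracy toward chance by exactly
  $(1-m)a + m/16$ for miss rate $m$ and true accuracy $a$ — or dropped
  (`impute_missing()`).  Both treatments are available because the
  difference between them bounds the imputation bias in any downstream
  number.

QC order is exclusion, then warm-up discard, then imputation; exclusion
statistics therefore never see imputed response times.

## Curves, normalization and the timestep mapping

`compute_curves()` aggregates timed trials into accuracy-vs-latency curves
with binomial standard errors $\sqrt{a(1-a)/n}$.  Curves are normalized by
untimed accuracy — the fraction correct on training trials
(`untimed_accuracy()`), computed per experiment by default or per observer
by option — so curves read as fractions of untimed performance and may
exceed 1.  A visualization-only chance point (6.25% for the 16-way task)
can be attached at time 0 (`add_chance_anchor()`); every metric strips it.

Model observers produce one prediction per (timestep, image).  Because the
number of timesteps equals the number of timed blocks, the default mapping
assigns timestep $i$ the $i$-th beep latency (`map_timesteps()`, mode
`"index"`).  An affine mode `time = a\,i + b`, $a > 0$, is provided for
analyses that allow the model its own processing speed and onset delay;
$(a, b)$ minimize the squared difference between model accuracies and the
linearly interpolated reference curve.  With the default non-linear
latency grid an exact recovery of the index mapping is impossible by
construction (no affine map passes through 500, 900, 1,100, 1,300,
1,500), so the fit is a compromise; the tests assert exact recovery on a
linear latency grid and approximate recovery on the default grid.  A flat
reference leaves $(a,b)$ unidentified and triggers a fall-back to index
mapping with a warning, breaking ties toward the smaller slope.

`timestep_flop_correlation()` checks the premise of the mapping: the
Pearson correlation between a network's ordinal timesteps and the
floating-point cost of its successive outputs, which should be high if
timesteps are to stand in for computational time.

## The three comparison metrics

**Curve-fit error.**  For two families of curves over the same $N_p$
perturbation levels and $N_t$ times,
$$e_{RMSE}(c_1,c_2) = \frac{1}{N_p}\sum_{p=1}^{N_p}
  \sqrt{\frac{1}{N_t}\sum_{t=1}^{N_t}\big(c_1[p,t]-c_2[p,t]\big)^2},$$
i.e. the RMSE across time, averaged across perturbation curves.  The
square root is applied per perturbation curve before averaging, so each
condition contributes its own RMSE; the result is symmetric, zero iff the
families agree, and satisfies the triangle inequality.  The unperturbed
condition (noise 0 = low-contrast gray, blur 0 = color) is always part of
the family.

**Category-wise correlation.**  Per-category SAT curves are flattened
into a single vector — categories in alphabetical order, then time
ascending, on both sides — and Spearman's rank correlation (average ranks
for ties) is computed.  Per-category curves pool over perturbation
conditions: this is the granularity at which per-point trial counts stay
workable (about 12 per category and latency in a 210-trial block), and
category-level comparisons are typically reported for a single-condition
experiment.  Zero-variance vectors yield a degenerate flag, never a
coerced number; negative correlations are preserved (clipping is a display
choice, not part of the metric).

**Steepness.**  The cumulative Weibull
$$a(t) = \gamma + (1-\gamma-\lambda)\big(1 - e^{-(t/\tau)^\beta}\big)$$
is fit to each curve (`fit_weibull()`), and steepness is the mean
plane-curve curvature $\kappa = |y''|/(1+y'^2)^{3/2}$ of the fitted curve,
evaluated by central differences on a uniform grid of 101 points spanning
the design's latency range (`steepness()`).  The default evaluation scale
is log-log, matching how such curves are usually displayed and giving two
useful invariances: rescaling all times (with $\tau$ alongside) and
multiplying all accuracies by a constant both leave the statistic
unchanged.  The latter is why `benchmark()` computes steepness from fits
to raw-unit curves — the value equals what a fit to the normalized curve
would give, while keeping the lapse parameter inside its natural bounds
($1-\lambda \le 1$).  Grid size, scale and range are configurable; the
grid/differencing defaults are this package's documented choice.  The
"average human" steepness row is a fit to the pooled (averaged) human
family by default; a per-observer-fit-then-average mode is available.

## Weibull fitting: numerics and identifiability

`fit_weibull()` minimizes bounded least squares with the guess rate fixed
at chance (1/16) by default, $\lambda \in [0, 0.5)$,
$\tau \in [\min t/10,\ 100 \max t]$, $\beta \in [0.05, 50]$, restarting
L-BFGS-B from a 5×5 grid of $(\tau, \beta)$ initializations; the best
residual wins and ties go to the smaller $\beta$.  On noise-free curves
generated from known parameters the fit recovers them to well under 1%.

Identifiability matters more than optimization here.  With five points and
binomial noise at 200 trials per point, the shape $\beta$ is recovered
with a median relative error below 10% only when the curve both leaves the
guess rate and approaches a high asymptote *within* the sampled 500–1,500
ms window (roughly $\tau \lesssim 850$ ms, $\beta \gtrsim 2.5$, lapse
$\lesssim 0.15$).  For curves that do not saturate in the window, the
lapse-scale trade-off is unconstrained and no estimator does better — we
verified that an independent optimizer on the same data reproduces the
same error medians to four decimals.  The parameter-recovery suite
therefore draws its ground-truth parameters from the identifiable regime
and this limitation is stated here rather than hidden: fitted $\tau$ and
$\lambda$ for slowly rising curves (e.g. heavily perturbed conditions)
should be read as a curve summary, not as meaningful parameter estimates.
Flat curves are flagged degenerate rather than fitted.

## What the synthetic generator emulates

`simulate_observer()` generates full sessions with the statistical
structure the analysis assumes: Weibull-shaped accuracy growth with
condition- and category-dependent difficulty, truncated-Gaussian response
jitter around the beep, latency-dependent missing responses, balanced
categories per block, and counterbalanced block order.  Defaults, chosen
once as representative of the paradigm:

* base psychometric curve $\gamma = 1/16$, $\lambda = 0.25$ (untimed
  accuracy ≈ 0.75, the observed ceiling for this task), $\tau = 900$ ms,
  $\beta = 1.6$ — a gradual rise spanning chance to near-ceiling across
  500–1,500 ms;
* perturbation grid per experiment: noise standard deviations
  {0, 0.04, 0.16} on grayscale, blur {0, 3, 10} on color (0.04 and 3.0
  being the canonical "small perturbation" strengths for this task), each
  with an asymptote scale and a $\tau$ multiplier so perturbed curves are
  lower and slower;
* miss probabilities 0.15 at 500 ms, 0.05 at 900 ms, 0.02 above —
  misses concentrate at the shortest latency, where responding in time is
  hardest.  Published per-block missing counts are not available in the
  main text of the literature this emulates, so these are uncalibrated
  free parameters;
* response-time jitter SD 50 ms, truncated to the recordable interval.

`simulate_model_observer()` emits per-timestep prediction tables from
three qualitative profiles spanning the behaviors reported for dynamic
networks: `gradual_wide` (smooth rise over a wide accuracy range, as for
cascaded networks), `steep_saturating` (a jump to the asymptote after the
first timestep, same endpoints as `gradual_wide` — the profile pair used
for the ordering check), and `shallow_low_range` (slow rise over a narrow
range).  Custom accuracy tables are accepted.

What the generator does **not** emulate: sequential dependencies
(learning, fatigue, post-error slowing), image-level difficulty beyond a
per-category multiplier, correlated errors across observers viewing the
same images, and motor-time variation.  Passing tests therefore show the
pipeline's arithmetic and statistical contracts are right under the
stated generative assumptions — not that real data meet those
assumptions.

## Problem sizes and reproducibility

Tests and the acceptance script run on cohorts of 3–8 synthetic observers
with full 1,100-trial sessions (smaller blocks in unit tests), 100
replicates for recovery suites, and 200 random cases for oracle
equivalences — sizes chosen so each property is measured with comfortable
statistical margins.  Every stochastic stage draws a child seed from one
global seed; identical (spec, design, seed) triples produce byte-identical
tables, and `run_simulate()` writes a manifest sufficient to regenerate
its outputs exactly.

## Known limitations

* The affine timestep mapping interpolates the reference curve linearly
  and assumes a monotone reference; heavily non-monotone references can
  produce slope/delay trade-offs with near-equal objective values (ties
  resolved toward smaller slope).
* Summaries use simple quartiles with a 1.5 × IQR outlier rule; no
  significance testing between models is provided, by design.
* The steepness recipe (grid, differencing, axes) is a documented default
  rather than a canonical standard; compare steepness values only across
  curves computed with identical settings.
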