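---
title: "Designing experience sampling studies of affect dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing experience sampling studies of affect dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esmdesign)
```

## The problem

Experience sampling (ESM) studies ping participants on their phones a few
times a day and ask how they feel right now, typically on a bounded slider
(here 0 = very unhappy to 100 = very happy). A person's stream of momentary
reports is then summarised into *affect dynamics* measures:

| Family      | Measure | Definition (per person, reports $x_1,\dots,x_n$ in time order) |
|-------------|---------|----------------------------------------------------------------|
| Trait       | mean    | $M = \sum_i x_i / n$ |
| Variability | SD      | $\sqrt{\sum_i (x_i - M)^2 / n}$ (population divisor) |
| Variability | relative SD | $SD / \sqrt{(M - l)(u - M)}$ for scale bounds $(l, u)$ |
| Instability | RMSSD   | $\sqrt{\sum_i (x_i - x_{i+1})^2 / (n-1)}$ |
| Instability | TKEO    | $\sum_i (x_i^2 - x_{i-1} x_{i+1}) / (n-2)$ |
| Instability | PAC     | share of successive changes with $|x_{i+1} - x_i| > d_{0.9}$ |
| Inertia     | AR(1)   | $\sum_i (x_i - M)(x_{i+1} - M) \,/\, \sum_i (x_i - M)^2$ |

$d_{0.9}$ is the 90th percentile of the absolute successive changes pooled
across *all* persons in the sample, so PAC is always read against a
sample-level yardstick.

Two design questions follow. How many reports per person are needed to
estimate each measure accurately, and does it matter *when* they are
collected? And how many participants and reports per participant are needed
to detect a correlation between a measure and some outcome? This package
answers both by simulation: subsample-versus-truth RMSE curves for
estimation accuracy, and Monte Carlo power over a grid of
(participants × observations) designs.

All measures are order-based: any two consecutive retained reports count as
"successive" whether they are one hour or one weekend apart. That is a
modelling decision inherited from the estimators themselves, and it is why
the synthetic generator (below) also places its serial dependence in report
order rather than in continuous time.

## Conventions and numerical choices

* **Timestamps** are timezone-naive local clock time, stored as
  UTC-labelled `POSIXct`. Time-of-day windows (morning 6 a.m.–12 p.m.,
  afternoon 12–4 p.m., evening 4–8 p.m., night 8 p.m.–6 a.m.) are meant in
  the participant's local time; nothing in the package ever converts
  between zones. Window boundaries are half-open so the four windows
  partition the day — a report at exactly noon is "afternoon".
* **SD divisor.** The population divisor $n$ is the default for both the
  within-person SD and the between-person benchmark SD; `divisor = "n-1"`
  switches to the sample convention. The relative SD uses the population
  maximum $\sqrt{(M-l)(u-M)}$, which is free of $n$ and therefore
  comparable across subsample sizes.
* **Percentiles** (the PAC threshold, bootstrap quantiles) use linear
  interpolation between order statistics (quantile type 7).
* **PAC threshold under subsampling.** By default $d_{0.9}$ is recomputed
  from the data actually in hand: per resampling replicate, the absolute
  changes of *all persons' subsamples of that replicate* are pooled and the
  percentile retaken, while the "true" PAC always uses the full-data
  threshold. `d90_mode = "fixed"` freezes the full-data threshold
  everywhere instead. Recomputation is the default because the threshold is
  defined on "the sample", and under a reduced design the sample *is* the
  subsampled data a researcher would hold.
* **Close sampling** scans contiguous runs of `n` consecutive reports whose
  adjacent gaps are all ≤ 24 h and keeps the run with the smallest
  first-to-last span; ties go to the earliest run, and runs are never
  stitched across a longer gap.
* **Distant sampling** minimises the total absolute deviation between the
  chosen report times and an equally spaced grid from the person's first to
  last report, solved exactly by dynamic programming with order
  preservation; ties again resolve to earlier reports.
* **Degenerate inputs** yield explicit `NA` markers, never a silent zero:
  AR(1) of a constant series (zero denominator), relative SD when the mean
  sits on a scale bound with zero SD (0/0), and any measure whose minimum
  series length (1 for the mean; 2 for SD, relative SD, RMSSD, PAC; 3 for
  TKEO and AR(1)) is not met. Persons with undefined values are dropped
  pairwise from downstream averages.

## Accuracy: subsample-versus-truth RMSE

A person's "true" measure is computed from their complete record; by
convention only persons with at least 50 reports enter this pool
(`min_full`). For a design with `n` observations per person,
`rmse_curve()` re-estimates the measure from subsamples and reports, per
person, $\mathrm{RMSE} = \sqrt{\mathrm{mean}_r (\hat\theta_r - \theta)^2}$
over replicates (default 1000; desk-scale runs in this vignette and the
tests use 150–200, always recorded in the output's `replicates` column).
Close and distant sampling define exactly one subset per person, so their
per-person error is a single $|\hat\theta - \theta|$. Per-person RMSEs are
averaged with equal weight per person, and a percentile bootstrap (2000
resamples, chosen for CI stability) over the per-person RMSEs gives the
95% interval.

The curves are read against between-person benchmarks
(`benchmark_thresholds()`): 1, 0.5, and 0.3 times the between-person SD of
the true measure. An average estimation error of one between-person SD
means within-person measurement noise is as large as the true differences
between people one hopes to study.

Time-window and day-filter sampling restrict the candidate reports before
random subsampling. Persons need at least 30 surviving reports
(`min_window`), and estimates receive a bias correction: the population
mean of the measure over all window-restricted records is aligned with the
population mean over all records by a single additive shift per measure
(`debias()`). The shift removes "time-window fixed effects" — affect runs
systematically higher in the evening — without touching the ordering of
persons. The correction is formulated so that the corrected
window-restricted full-record estimates have exactly zero population-mean
bias; raw uncorrected curves are available via
`debias_estimates = FALSE`.

## Power: Monte Carlo over a design grid

`power_cell()` estimates the power to detect a Pearson correlation
`r_target` between a measure and an outcome under a design with
`n_participants` persons and `n_obs` reports each:

1. Draw an outcome vector against the *full* person pool's true measure
   values: standardized truths mixed with Gaussian noise orthogonalized
   against them, $r\,\tilde y + \sqrt{1-r^2}\,\tilde\varepsilon$, so the
   sample correlation across the pool equals `r_target` exactly
   (`mode = "exact"`; `"population"` uses raw normal noise and attains
   `r_target` only in expectation).
2. Resample `n_participants` persons with replacement and pair each with
   their outcome value.
3. Re-estimate the measure for each sampled person from a fresh random
   subsample of `n_obs` of their reports (`n_obs = NULL` uses the true
   values — the noiseless case used for calibration checks).
4. Test with a two-tailed t-test on the Pearson correlation
   ($t = r\sqrt{(n-2)/(1-r^2)}$, $n-2$ df) and count the dataset as a
   success only if $p < \alpha$ *and* $r > 0$.

Power is the success proportion over `n_sims` simulated datasets (default
2500), with Monte Carlo standard error $\sqrt{p(1-p)/n_{\mathrm{sims}}}$.
Counting only positive rejections means the null rejection rate is
$\alpha/2$, not $\alpha$ — a property the test suite checks. With
noiseless measures this machinery reproduces the Fisher-z closed form
$\Phi(\mathrm{atanh}(r)\sqrt{n-3} - z_{1-\alpha/2})$ to within Monte Carlo
error.

A design note: the outcome is drawn against the full pool each simulation
and participants are then resampled (step 1 then 2). Generating an
exact-correlation outcome against the *resampled* participants instead
would pin every simulated dataset's sample correlation at `r_target` and
make power degenerate to a step function; that pairing
(`pairing = "resampled"`) is therefore only sensible together with
`mode = "population"`, and the pool-first pairing is the default.

`power_grid()` sweeps the canonical grids — participants 10, 20, 40, …,
5120 and observations 5, 10, …, 50, at weak/medium/strong effects
$r \in \{0.10, 0.30, 0.50\}$ — and `minimal_designs()` extracts, per
number of participants, the smallest number of observations reaching a
target power (default 80%). Monte Carlo noise can make that frontier
locally non-monotone, so an isotonic cleanup enforces the minimal
observation count to be non-increasing in the number of participants.
`effect_benchmarks()` tabulates measure-covariate correlations from
full-record measures to help anchor a plausible `r_target`.

## The synthetic generator

No public ESM dataset matches the regime the package targets, so
`generate_dataset()` builds one with known ground truth. Per person $i$:

* a notification schedule with `beeps_per_day` (default 4) uniform-random
  instants per day inside the day window (default 9 a.m.–10 p.m.), all
  consecutive gaps ≥ 1 h — drawn as sorted uniforms on the gap-reduced
  window and spaced back out, which is uniform over the feasible
  configurations;
* a latent state $s_k = \phi_i s_{k-1} + \sigma_i \epsilon_k$, a
  stationary AR(1) *in beep order* — matching the order-based estimators —
  initialised from its stationary distribution;
* an observed value $\mu_i + A\cos\!\big(2\pi(h_k - h_{\mathrm{peak}})/24\big)
  + w\,\mathbb{1}[\mathrm{weekend}] + s_k$, clipped to the scale bounds
  and rounded to an integer (slider semantics).

Person-level heterogeneity: $\mu_i \sim N(60, 15^2)$,
$\sigma_i \sim \mathrm{lognormal}(\log 9, 0.35)$ (median within-person
innovation scale ≈ 9 scale points), $\phi_i \sim N(0.35, 0.15^2)$
truncated to $(-0.95, 0.95)$, diurnal amplitude 5 peaking at 18 h, weekend
shift +2. The population distributions of the real study are unpublished;
these defaults are plausible placeholders for momentary happiness on a
0–100 slider (mildly positive average mood, within-person SD around 10–15,
moderate inertia) and are deliberately mid-scale so that boundary clipping
is essentially inactive. The generator covers the features the estimators
care about — heterogeneity, serial dependence, diurnal and weekend
structure, integer slider output, irregular gap-constrained schedules —
but not missingness/compliance, multi-item questionnaires, or
continuous-time dynamics (an elapsed-time-aware process is out of scope
because the measures themselves ignore elapsed time). Passing tests
therefore validate the *machinery* on data with known truth; they do not
certify any particular real population's numbers.

## What the test suite establishes

Problem sizes below are the package's validation choices; all run on one
desk CPU.

* The seven measure implementations agree exactly with hand computations
  and an independent naive-loop oracle on 1000 random series.
* Close/distant selection equals exhaustive search on 500 random short
  series.
* The power engine's null rate is $\alpha/2$ (4000 simulations, 200
  participants) and its noiseless power matches Fisher-z at $n = 80$,
  $r = 0.3$ (2000 simulations).
* Random-sampling RMSE is non-increasing in the number of observations
  from 3 to 30 for all seven measures (200 persons × 240 reports, 200
  replicates), and for the mean on serially independent data it tracks
  $\sigma_{\mathrm{within}}/\sqrt{n}$ within 15% (the deviation is the
  finite-record correction $\sqrt{1 - n/N}$).
* With diurnal structure and strong inertia, close sampling is the least
  accurate strategy for mean, SD, and relative SD at 10 observations —
  consecutive reports are serially correlated and under-cover the diurnal
  cycle.
* The bias correction zeroes the population-mean gap to machine precision
  and preserves ranks; generator ground truth ($\mu_i$, $\phi_i$,
  stationary SD) is recovered within 10% at 60 days × 4 beeps.

## Worked example

```{r example}
cfg <- synthetic_config(n_persons = 60, days_per_person = 30, seed = 42)
sim <- generate_dataset(cfg)
sim$data

truths <- true_measures(sim$data)
head(truths, 3)

set.seed(43)
curve <- rmse_curve(sim$data, measures = "mean", n_obs = c(3, 5, 10, 20),
                    replicates = 150)
curve

bench <- benchmark_thresholds(truths)
thr <- bench$threshold[bench$measure == "mean" & bench$multiple == 1]
min_n_for_accuracy(curve, thr)

set.seed(44)
power_cell(sim$data, "mean", n_participants = 200, n_obs = 20,
           r_target = 0.3, n_sims = 400)
```

## Known limitations

* Accuracy and power numbers are properties of the dataset they are run
  on; on synthetic data they validate the machinery, not any specific
  population. Run the same functions on your own pilot data for
  study-specific answers.
* The framework targets a single unidimensional affect item and Pearson
  correlations with person-level outcomes; mixed-effects outcome models,
  multi-dimensional affect, and context-triggered sampling are out of
  scope.
* "True" values are themselves estimates from finite records; with the
  default 50-report floor the truth error is small relative to the
  subsample error but not zero.
* Boundary clipping in the generator can bias parameter recovery when
  person means sit near the scale bounds; validation uses mid-scale
  parameters on purpose.
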