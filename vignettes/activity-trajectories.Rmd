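---
title: "Methods: tracker-based activity patterns and trajectory clustering in inflammatory arthritis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracker-based activity patterns and trajectory clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement model

actitraj analyses minute-level step counts from a wrist-worn tracker in
cohorts of patients with rheumatoid arthritis (RA) or axial
spondyloarthritis (axSpA). The tracker's native unit is the **cadence**:
steps recorded in one clock minute. Cadence thresholds translate minutes
into physiological intensity:

* cadence >= 20 steps/min — an *active* minute (below 20 is considered rest);
* cadence >= 100 steps/min — *moderate-to-vigorous* physical activity (MVPA);
* cadence >= 130 steps/min — *vigorous* activity.

All comparisons are inclusive (`>=`), including the downstream
recommendation thresholds (>= 150 MVPA min/week, >= 75 vigorous min/week,
>= 10,000 and >= 7,000 steps/day). These cut-offs are configurable
(`cadence_thresholds()`, `who_status()`) but the defaults are the values
above.

Each participant is observed over a fixed **90-day window starting the
first Monday strictly after device activation**. "Strictly after" means an
activation on a Monday starts the *following* Monday; the alternative
reading would only shift the window by at most seven days, and the choice
is isolated in `build_window()`. A calendar day runs from 00:00 to 23:59
local civil time; no timezone shifts are applied within a window.

Two validity rules come from the study design this package operationalizes:

* **Full-day rule** — a day is analyzable only if at least 8 hours (480
  minutes) elapse between its first and last stepped minute. Only minutes
  with at least one step can witness wear, so "8 h recorded" is
  operationalized on the first-to-last-step span; a day with a single
  stepped minute has span 0. Minutes with zero steps are indistinguishable
  from non-wear minutes, and no within-day non-wear imputation is
  attempted.
* **Adherence rule** — a participant is analyzable only with at least 60
  complete days of the 90 (boundary inclusive). Excluded participants
  still contribute to the adherence summary, where a day counts as *worn*
  if it has any record at all — the laxer definition is deliberate, since
  wearing behaviour and data validity are different questions.

Derived daily patterns: total steps, the morning-step fraction (steps
before 12:00 over total steps, a proxy for morning stiffness), active
minutes, MVPA minutes, vigorous minutes, and steps accumulated in MVPA
minutes. Weekly MVPA is the participant's daily mean multiplied by 7.
Published cohort tables are internally inconsistent on this point (a
16 min/day mean alongside a 106 min/week mean, where 16 x 7 = 112), and
the weekly aggregation behind such numbers is typically unstated; both
aggregations are implemented (`weekly = "daily_mean_x7"` or
`"calendar_week"`, which rescales each observed week to 7 days before
averaging) and the daily-mean convention is the default.

## Missing-day imputation

For sensitivity analyses, each missing (non-complete) day of a trajectory
is imputed by the mean of the participant's *observed same weekdays*;
windows all start on Mondays, so column `d` of the trajectory matrix is
weekday `(d - 1) mod 7` for every participant. Observed cells are never
touched. A participant with no observed instance of some weekday falls
back to their overall mean; every fallback is recorded in the result's
`fallbacks` attribute for audit. The companion analysis path clusters the
*incomplete* matrix directly with available-case distances (below), and
the pipeline reports the agreement between the two assignments as its
imputation-sensitivity diagnostic.

## Trajectory clustering

Trajectories (90-day vectors of one daily feature, MVPA minutes by
default) are partitioned by K-means adapted to longitudinal data: Lloyd's
algorithm with plain Euclidean distance between whole trajectories, no
time warping and no standardization (z-scaling is available but off by
default, matching common practice for single-feature trajectories).
Numerical conventions, each of which is tested:

* initial centroids are `k` distinct randomly chosen trajectories;
  `n_starts = 20` random starts by default, best total within-cluster sum
  of squares wins;
* ties in assignment go to the lowest cluster index;
* a cluster that empties during iteration is re-seeded from the point
  farthest from its current centroid, which is *forced* into the cluster —
  forcing guarantees progress even on degenerate data with many duplicate
  trajectories — and every re-seed is counted on the result;
* after convergence clusters are relabelled by ascending centroid grand
  mean, so cluster 1 is always the low-activity cluster;
* the within-cluster sum of squares is non-increasing across iterations
  (asserted in the test suite), and on instances small enough to
  enumerate, the multi-start fit attains the exhaustive-partition optimum.

With missing cells (`na_action = "available"`), squared distances are sums
over a trajectory's observed days rescaled by `90 / n_observed`, and
centroids are means over the observed cells of member trajectories.

Partition quality uses the Calinski–Harabasz ratio
`(B / (k - 1)) / (W / (n - k))` on between-/within-cluster dispersion of
whole trajectories; `select_k()` scans a range of `k` and returns the
maximizer (undefined at `k = 1`, reported as `NA`).

**A structural caveat on selecting k.** The replication pipeline fixes
`k = 3` (a low/moderate/high structure with proportions near 54/43/3).
With a 3% smallest class and realistic day-to-day variability, the
Calinski–Harabasz criterion usually prefers `k = 2` on such data: the
`k - 1` divisor halves the between-cluster credit of adding a third
cluster, while a tiny far cluster removes only a few points' worth of
within-cluster dispersion. An analysis of the crossover shows the
criterion only favours `k = 3` here when the day-to-day coefficient of
variation of MVPA falls below roughly 0.16 — far smoother than human
activity ever is (weekday/weekend structure alone exceeds it). `select_k()`
therefore implements the criterion faithfully and recovers the true `k` on
well-separated data, but on this cohort geometry the fixed `k = 3` of the
main pipeline should be understood as a design choice, not a data-driven
one, and the accompanying test records the criterion's actual behaviour
rather than forcing the desired answer.

## Inference

* **Longitudinal group comparison** (`fit_group_lmm()`): linear mixed
  model on day-level features over days 1..90 — fixed effects for disease
  group, day index and the baseline covariates (sex, age, BMI, disease
  duration, biologic therapy, employment, patient global assessment);
  random intercept and random day slope per participant; REML. With the
  `nlme` engine, heteroscedasticity is modelled by the power variance
  function (residual SD proportional to a power of the fitted mean).
  "When observed" needs an operational trigger: the homoscedastic fit is
  screened by regressing |residual| on fitted values, and the variance
  function engages at p < 0.05. The step-count model uses this path. For
  MVPA minutes, whose fitted values approach zero, the varPower profile is
  numerically fragile and an order of magnitude slower, so the pipeline
  fits MVPA with the `lmerTest` engine without a variance function; both
  engines expose the same contract and agree within statistical resolution
  (tested). Age is kept continuous here.
* **Recommendation fulfillment and low-cluster membership**
  (`fit_who_logistic()`, `fit_low_cluster_logistic()`): logistic
  regressions adjusted on the same covariates, odds ratios with 95% Wald
  intervals. In the cluster model, age enters dichotomized at >= 60 years
  and the BMI odds ratio is expressed per 5-unit increase
  (`exp(5 * beta)`) — reporting conventions of the field; the asymmetry
  against the continuous-age mixed model is deliberate and documented.
  Patient global assessment enters raw on its 0–10 scale. Degenerate
  designs are surfaced, not hidden: single-class outcomes error, aliased
  terms and suspected separation set flags on the result. No
  multiple-testing correction is applied anywhere; reports should say so.
* **Design sample size** (`sample_size_two_means()`): the
  normal-approximation formula
  `n = ceiling(2 ((z_{1-a/2} + z_{1-b}) sd / delta)^2)`, floored at 1.
  At delta = 1500 steps/day, sd = 3300, 80% power, 5% two-sided alpha it
  gives 76 per group. A t-based fixed-point iteration is available and
  cross-checked against `power.t.test`.

## The synthetic cohort: what it emulates, and what it does not

No raw data from the study this package operationalizes are publicly
deposited, so `generate_cohort()` is a first-class, tested module that
emulates the study conditions with known ground truth:

* three latent MVPA classes, constant in mean over time, at 7.2 / 23.8 /
  49.4 min/day in proportions 54.1 / 42.7 / 3.2%;
* class steps/day means 6000 / 8310 / 10300 with within-class SD 1900 —
  chosen once so the class-weighted cohort mean is ~7124 steps/day, the
  cohort SD ~2300, and the fractions above 10,000 and 7,000 steps/day land
  near 10% and 50%;
* between-participant within-class MVPA SDs 3.0 / 4.5 / 8.5 min/day.
  Published per-cluster SDs describe the *output* of a k-means partition
  (truncated mixtures), not generating classes; these generating values
  keep baseline class overlap near 3%, the regime in which class recovery
  at adjusted Rand >= 0.8 is meaningful;
* day-to-day variability: gamma-distributed daily targets with CV 0.5
  (MVPA minutes) and 0.3 (steps) — ordinary human variability;
* weekly periodicity: Sundays scaled by 0.75, with the week renormalized
  so class means stay week-average levels;
* non-wear: per-day missingness with cohort mean 0.12, drawn
  per-participant from a Beta distribution with concentration 4 — the
  heterogeneity is what makes ~12% of participants fall below 60 complete
  days (emulating a 178-included / 157-analyzable flowchart) while mean
  wear stays at 88% of days (~79 of 90); partial days (records confined to
  a 1–7 h window) occur at rate 0.04;
* covariates drawn from group-specific distributions (RA older, mostly
  female; axSpA younger, mostly male; BMI ~25 (4.5) kg/m2, PtGA 0–10,
  DAS28/BASDAI carried per subgroup);
* the BMI–activity effect acts through **class membership**: an ordered
  logit on centred BMI (0.15/unit by default) whose intercepts are
  calibrated numerically against the realized BMI draw so marginal class
  proportions are preserved, plus a mild multiplicative steps/day
  decrement (-1%/unit). The class-mediated route was a deliberate design
  choice: with a purely continuous multiplicative effect, the
  participants whose BMI drags them across a class boundary are exactly
  the ones a clustering then "misclassifies" relative to their latent
  label, so effect recoverability and class recoverability destroy each
  other; routing the effect through membership lets both hold at once.

Within a day, minutes are placed by a fixed diurnal profile (zero before
06:00 and after 23:00, peaks around 08:00 and 18:00–19:00, ~34% of
weighted mass before noon) and band-specific cadence distributions
(MVPA: 100 + floor(Gamma(2, 10)); active: 20 + capped floor(Gamma(1.6, 16));
light: 1–19 with geometric decay). The study this emulates reports no
within-day activity distribution, so the diurnal shape is a free modelling
choice that produces the right daily aggregates and a ~32% morning-step
fraction; it must not be read as validated against real within-day
behaviour. Likewise out of scope: device artifacts (false steps from arm
movement, sync loss) beyond whole-day/partial-day missingness,
autocorrelated non-wear streaks, seasonal trends, and any
motivational-feedback dynamics. Passing tests on this generator show the
pipeline is correct and well-calibrated *under these conditions*; they
cannot show robustness to artifacts the generator does not model.

`resolution = "day"` skips the within-day placement but shares the
day-level random draws on the same RNG path, so statuses and daily
MVPA/active minute counts are identical to the minute-level cohort at the
same seed (asserted in tests) while daily step totals agree in
distribution (the aggregate band sums use the exact Gamma-sum for MVPA and
a central-limit approximation for the other bands). The day mode exists so
that replicated simulations stay cheap.

## Problem sizes used by the test suite

Chosen as the package's own verification design: class-mean convergence at
n = 300; Sunday periodicity at n = 100; k-selection and class recovery on
20 seeded replicates of the default n = 157 cohort; brute-force partition
oracles on 20 instances with at most 10 trajectories; mixed-model size and
power at 200 replicates of 60 + 60 and 76 + 76 participants (day
resolution, lmerTest engine, no variance function — the variance function
is exercised separately on single fits); BMI recovery and null coverage at
120 replicates each of the default cohort. One full minute-resolution
pipeline run (178 participants, ~3 million minute records) backs the
end-to-end and acceptance paths.

## Known limitations

* K-means with Euclidean distance favours spherical, similarly sized
  clusters; genuinely different within-cluster variances (the high class
  is much noisier) are handled only implicitly. Model-based alternatives
  (growth mixture models, latent-class mixed models) are out of scope.
* The Calinski–Harabasz criterion under-selects small far clusters on
  noisy trajectories (see above); treat automatic k selection on real
  cohorts with caution.
* Morning-fraction analyses are limited by the absence of wake-time
  information; a zero-step full day (impossible under the full-day rule)
  would have an undefined morning fraction and is recorded as missing.
* The varPower residual model is fragile when fitted means approach zero;
  count-like features at low levels are better served by the engine
  without a variance function, or in principle by a generalized model
  outside this package's scope.
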