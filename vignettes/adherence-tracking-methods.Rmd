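---
title: "Methods: PDC adherence, tracking metrics, and their association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PDC adherence, tracking metrics, and their association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adheretrack)
```

## The scientific question

Do people who actively track health behaviours (steps, sleep, weight, food)
take their chronic-disease medication more reliably? The package implements
the full measurement chain needed to ask that question from insurance claims
and wearable logs: condition cohorts from diagnosis codes, medication
adherence as proportion of days covered (PDC), per-individual tracking
metrics, and adjusted logistic models linking the two. Because real pharmacy
claims of this kind are proprietary, everything is exercised on a synthetic
population whose generating parameters — including the tracker–adherence
odds ratio itself — are known, so the pipeline can be held to quantitative
recovery standards rather than plausibility checks.

## Study calendar and day arithmetic

Three windows drive everything (`study_calendar()`):

* **supply period** 2015-01-01 → 2015-06-01: establishes qualifying fills
  and the medication each individual still holds when the main window opens;
* **analysis period** 2015-06-01 → 2016-06-01: adherence and tracking are
  measured here. Treated as the half-open interval `[2015-06-01,
  2016-06-01)`, it spans exactly **366 days** (it contains the 2016 leap
  day), and that count is the fixed-PDC denominator. A `denominator = 365`
  override supports comparison with implementations that fix the
  "one year" denominator at 365 regardless of calendar.
* **diagnosis window** 2005-01-01 → 2015-09-01 (inclusive): qualifying
  diagnosis dates.

Dates are converted once to integer day offsets from 2015-01-01 and all
intervals are half-open, so lengths are plain differences and no day is ever
counted twice. This is the single most defect-prone part of PDC code, which
is why an independent day-grid oracle (literally marking covered days one at
a time) backs every interval computation in the test suite, over thousands of
randomized fill histories with overlaps and carryover.

## Cohort inclusion

A person enters a condition cohort when all three hold: (1) insurance
coverage starts on or before the supply period and lasts through the
analysis period — read strictly, with no grace gap, since the data carry no
gap semantics; (2) at least one diagnosis code in the window matches the
condition's ICD-9/ICD-10 families (prefix matching, dot- and
case-insensitive; ranges like E08–E11 and 401–405 expand to their
three-character families; dyslipidemia uses the specific families 272.0/.2/.4
and E78.0/.2/.4/.5); (3) at least one fill of a condition-relevant drug
class in supply ∪ analysis period. Multi-condition individuals join every
cohort they qualify for and contribute one row per condition to pooled
models. `build_cohort()` returns a per-individual attrition table so each
filter decision is auditable; a 12-individual handcrafted fixture in the
tests pins every rule to a hand-computed decision.

## PDC computation

Fills of one drug class **stockpile**: a refill collected before the current
supply runs out begins coverage when that supply is exhausted. This is the
standard "medication on hand" reading; the alternative of unioning literal
fill intervals is available (`overlap = "union"`) for sensitivity analyses.
Carryover is nothing special — supply-period fills simply enter the same
chain. Coverage (and the variable window) is truncated at the analysis end;
supply extending past the study is discarded, since adherence is defined
only over the study span. Drug classes never share supply.

The **variable window** runs from the first analysis-period fill to the
*stockpiled* supply end of the last fill (consistent with the numerator's
coverage rule), capped at the analysis end, and requires at least two
analysis-period fills — otherwise the ratio is trivially 1. That eligibility
rule is applied **per drug class**, and the condition-level variable PDC
averages only eligible classes (weights = personal window lengths); with the
window defined per class, a per-condition reading would have no natural
window to weight by. Classes filled only in the supply period still
contribute a fixed-PDC term: their carryover coverage in the analysis window
is genuine, if small.

Adherent means condition-level PDC ≥ 0.80, threshold inclusive. The
sensitivity classification (any single class ≥ 0.80) is computed alongside.

## Tracking metrics

Only `source == "tracker"` rows are used; phone-source step counts are
collected passively and say nothing about a daily decision to track, so they
are dropped entirely rather than only from the step metrics.

With `k` distinct logged days (any activity) over span `n` = last − first
+ 1, the raw ratio is `r = k/n`. The span is inclusive so a single-day
tracker gets `r = 1` at `n = 1` instead of a division by zero; at realistic
spans the +1 is negligible. The **adjusted tracking ratio** shrinks `r`
toward the population mean `r̄` (unweighted mean over all individuals with a
log):

```
adjusted = (k + 10 r̄) / (n + 10)
```

This is the canonical definition. It is worth being precise about its
Bayesian reading: under a Beta prior with **mode** `r̄` and total weight
`α + β = 12`, the posterior mode (MAP) is exactly the formula above. A prior
constrained instead to **mean** `r̄` with `α + β − 2 = 10` gives MAP
`(k + 12 r̄ − 1)/(n + 10)`, which coincides with the canonical formula only
at `r̄ = 0.5`. Both are implemented (`variant = "map_mean"`), the canonical
form is the default and the one every downstream computation uses. Either
way the estimator sits strictly between `r` and `r̄` and converges to `r` as
`n` grows — properties the tests check directly.

Steps per week tracked divides total steps by the number of **distinct
Monday-start calendar weeks** containing a step log — the natural count of
"weeks during which they tracked" — with `ceiling(span/7)` available as a
config alternative. Metrics models are restricted to individuals with two
logs at least 10 days apart (inclusive: a span of exactly 10 qualifies),
because day-to-day logs are strongly autocorrelated and the separation
guarantees two effectively independent observations.

## Association models

All models are maximum-likelihood logistic fits (`stats::glm`) with Wald
inference: z from the observed information, 95% CI = exp(β ± 1.96 SE),
significance at p ≤ 0.05, no multiplicity correction (each model is reported
on its own terms — a deliberate fidelity choice, flagged as a limitation).
"Controlling for age and sex with an interaction term" is implemented as
age + sex + age×sex, with a switch to drop the product term; age enters in
years, continuous and uncentred (the under/over-50 split is a reporting
grouping, not a model term). Per methodology the suite fits 11 models:
overall tracker, 3 per-condition, 4 per-activity, 2 single-metric and 1
combined metrics model; empty scopes (e.g. no food loggers) are skipped with
a warning rather than an error. Step counts enter per day tracked in
thousands — `steps_per_week / 7 / 1000` — giving coefficients of sane
magnitude, and are reported per 2000 steps via `scaled_or()`; the per-day
scale is the default because the rescaled effect is quoted per
steps-per-day increment. Quasi-complete separation is detected from fitted
probabilities pinned at 0/1 and surfaces as `converged = FALSE`.

Group contrasts of PDC by age group and sex use Welch's unequal-variance
t test with Satterthwaite degrees of freedom.

## The synthetic generator

Each individual draws an adherence propensity `a ~ Beta(4, 1.5)` (mean
0.73, right-skewed, shared across all their drug classes) and a daily
tracking rate `p ~ Beta(3, 2)`. Refills chain: the next fill lands at the
previous supply's exhaustion plus a geometric gap with mean
`(1/a − 1) × days_supply`, so `a = 1` refills gaplessly and the long-run
covered fraction is ≈ `a`. 85% of chains start at a uniform day of the
supply period (prevalent users — without this, uniformly-late first fills
would mechanically crush fixed PDC in a way no real prevalent cohort shows);
the rest start inside the analysis period. Because gaps are nonnegative the
chain's coverage intervals are disjoint, so the generator knows each class's
fixed PDC in closed form — that is the ground truth stored in `truth`.

**Effect injection.** Tracker adoption is logistic in a baseline (default
0.10), an age slope (younger individuals adopt more — an exposure-side
effect only, so it cannot confound), and the injected log-odds times the
individual's *true fixed-methodology adherent indicator*. Injecting on the
indicator rather than on the continuous propensity is deliberate: by the
symmetry of the odds ratio, the injected value then *is* the tracker ↔
adherent conditional odds ratio, exactly the estimand of the downstream
logistic models, with no attenuation through the 0.80 dichotomisation. An
injection on standardised `a` would leave the recoverable OR an unknown
function of the dichotomisation and the PDC noise — untestable as a
recovery target. The default injected OR is 1.33, and the baseline adoption
probability of 0.10 (an order of magnitude above the ~1% device-linkage
rates seen in insured populations) is chosen once so that the tracker
subgroup of a few-thousand-person simulation is large enough for stable
odds-ratio estimation.

Trackers get a tenure window from a uniform start day to the analysis end
and log on Bernoulli(`p`) days; owned activities (steps 85%, sleep 55%,
weight 20%, food 12%) are all logged on a logging day. Step counts are
lognormal (median 7000/day). A small fraction of individuals additionally
carry phone-source step rows, which the tracking module must ignore. All
randomness derives from per-individual substreams seeded by `(seed, id)`,
so bundles are byte-identical across runs and stable under any generation
order.

**What the generator does not emulate** — and therefore what passing tests
do not establish about real data: ICD code frequencies, seasonality in
steps or tracking, medication switching and prescriber-advised
discontinuation, dose changes, plan heterogeneity, device brands, and any
adherence–tracking dependence beyond the single injected adoption effect.
In particular the generator injects **no** within-tracker association
between tracking *frequency* and adherence, so the metric-model ORs on
synthetic data are null up to noise; those models are validated through the
formula-level and calibration tests, not through a synthetic effect.

## Problem sizes and numerical choices

The validation suite runs at sizes chosen to balance statistical resolution
against desk-scale runtimes: the oracle comparison uses 1000 randomized fill
histories (fill counts 0–12, supplies 7–90 days, overlaps and carryover
included); the fixed-below-variable ordering check uses one default cohort
of n = 5000; effect recovery uses 50 replicate cohorts of n = 5000 with an
injected OR of 1.5 on a single-condition, single-class configuration (so
the truth indicator and the measured outcome coincide exactly and the
recovery target is sharp); null calibration uses 100 replicates of
n = 2000. Wald CI coverage is checked over 200 direct logistic simulations.
Ties and degenerate inputs all resolve to explicit values rather than
errors where a value is meaningful: zero fills give an absent PDC,
single-fill classes an absent variable PDC, phone-only loggers are
non-trackers, and an all-identical Welch contrast returns t = 0, p = 1.

## Known limitations

Beyond the generator's realism limits above: PDC is an indirect adherence
measure (filling is not taking); the association models are deliberately
associative — no causal claims, no propensity adjustment; continuous
coverage is read with zero gap tolerance; and the condition-level fixed PDC
averages classes equally, which weights a barely-filled class the same as a
mainstay therapy. Each of these mirrors a standard practice in
claims-based adherence research rather than a technical constraint, and the
config switches (`denominator`, `overlap`, `week_rule`, `interaction`)
expose the main alternatives.
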