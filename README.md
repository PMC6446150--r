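# adheretrack

Claims-based analysis of the association between **medication adherence** and
**digital activity tracking** for chronic conditions (diabetes, dyslipidemia,
hypertension), built as a tested R package plus a set of analysis drivers.
It is aimed at health-services and adherence researchers who work with
pharmacy-claims data and wearable-device logs, and at anyone who needs a
validated, ground-truthed implementation of proportion-of-days-covered (PDC)
arithmetic.

Real claims data of this kind is proprietary, so the package ships a
synthetic-data generator that emulates the joint structure of demographics,
diagnosis histories, refill chains and daily tracking logs — with known
ground truth, including a configurable injected odds ratio linking tracker
adoption to adherent status — and the whole pipeline is validated against
that truth and against brute-force oracles.

## Methods in brief

**PDC.** For each individual and drug class, pharmacy fills
(day *t<sub>j</sub>*, supply *s<sub>j</sub>*) cover days by *stockpiling*:
each fill's coverage starts at max(*t<sub>j</sub>*, end of previous
coverage) and runs *s<sub>j</sub>* days, so early refills extend rather than
overlap coverage; supply-period fills carry over into the analysis window.

- *Fixed PDC* = covered days in the analysis period ÷ the full period length
  (366 days for 2015-06-01 → 2016-06-01); a lower bound on adherence.
- *Variable PDC* = covered days ÷ length of [first analysis-period fill,
  end of the last fill's stockpiled supply), requiring ≥ 2 analysis-period
  fills; an upper bound.

Condition-level PDC is the mean of class PDCs (fixed) or the
window-length-weighted mean (variable); *adherent* means condition-level
PDC ≥ 0.80. A sensitivity rule classifies anyone with ≥ 1 class PDC ≥ 0.80
as adherent.

**Tracking.** With *k* logged days over an inclusive span of *n* days, the
raw tracking ratio is *r = k/n*; the empirical-Bayes **adjusted tracking
ratio** shrinks it toward the population mean ratio r̄:

    adjusted r = (k + 10 r̄) / (n + 10)

i.e. a Beta-binomial point estimate whose prior is worth 10 days of
observation. Steps per week tracked divides total (tracker-device) steps by
the number of distinct Monday-start calendar weeks with a step log.

**Association.** Logistic regressions of adherent status on tracker status
(overall, per condition, per activity) and on the tracking metrics
(restricted to individuals with two logs ≥ 10 days apart), adjusted for age,
sex and their product term, with two-sided Wald tests and 95% CIs; effects
are rescaled to interpretable increments (per 0.5 adjusted-ratio units, per
2000 steps per day tracked).

## Worked example

```r
library(adheretrack)
cal <- study_calendar()

# two 30-day fills, the second picked up 20 days into the first
f <- fixed_pdc(c(151, 171), c(30, 30), cal)   # day 151 = 2015-06-01
f$covered; f$denominator; f$pdc
#> 60 / 366 = 0.1639      (stockpiling shifts the second fill to day 181)

v <- variable_pdc(c(151, 191), c(30, 30), cal)
v$covered; v$denominator; v$pdc
#> 60 / 70 = 0.8571       (personal window: first fill to supply exhaustion)

# end-to-end on a synthetic cohort
res <- run_pipeline(pipeline_config(sim = sim_config(n_individuals = 2000, seed = 1)))
res$report$adherence_summary[, c("condition", "fixed_pdc_mean", "variable_pdc_mean")]
#>      condition fixed_pdc_mean variable_pdc_mean
#>       diabetes          0.691             0.797
#>   hypertension          0.678             0.798
#>   dyslipidemia          0.680             0.800
```

The fixed means sit below the variable means for every condition — the
expected lower-bound / upper-bound relationship of the two methodologies.
With the default injected adoption–adherence odds ratio of 1.33, the overall
tracker-vs-nontracker models on this cohort estimate OR 1.42 (95% CI
1.06–1.89) for fixed adherent status and 1.36 (1.00–1.83) for variable —
consistent with the injected effect at this sample size.

The numbered drivers under `analysis/` run the same workflow stage by stage
(simulate → cohort → adherence → tracking → association → report) and leave
their tables under `results/`.

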