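---
title: "Trial-based cost-effectiveness analysis of psychotherapy session frequency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-based cost-effectiveness analysis of psychotherapy session frequency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbcea)
```

## What this package models

`tbcea` implements a trial-based economic evaluation comparing twice-weekly
with once-weekly psychotherapy sessions (CBT or IPT) for adult depression
over 12 months, from a societal perspective. The estimands are adjusted
between-group differences in costs and in four effect outcomes — depression
severity (BDI-II), quality-adjusted life-years (QALYs), and physical and
social functioning (RAND-36 PFS/SFS) — combined into incremental
cost-effectiveness ratios (ICERs), cost-effectiveness planes and
cost-effectiveness acceptability curves (CEACs).

Because patient-level trial data of this kind cannot be shared, the package
ships a synthetic trial generator that reproduces the *design* of such a
study — a 2x2 factorial RCT (session frequency x therapy type), cell sizes
49/49/47/55, nine sites, block randomisation stratified by depression
severity (BDI-II >= 29) and site, assessments at months 0/3/6/9/12 — so that
every stage of the analysis pipeline can be exercised and validated
end-to-end on data with known truth.

## Outcome construction

**Utilities and QALYs.** EQ-5D-5L profiles are converted to utilities by an
additive value set (tariff): utility = 1 minus the sum of per-dimension
level decrements. The Dutch tariff is proprietary input the user supplies as
a decrement table via `read_value_set()`; the package ships a clearly
synthetic illustrative set (`example_value_set()`, minimum utility -0.29)
for tests and examples. QALYs are the area under the utility-time curve:
for each pair of consecutive measurements the mean of the two utilities is
multiplied by the time in years between them and the products are summed.
Assessment months map to years as months/12 exactly (0, 0.25, 0.5, 0.75, 1).
Utilities below zero are allowed and QALYs are not floored. This module
requires complete trajectories: missing utilities are handled upstream by
multiple imputation, not by interpolation, which matches the analysis
ordering (impute first, then construct annual outcomes).

**Functioning scores.** RAND-36 subscale raw sums are linearly transformed
to 0-100 (`subscale_score()`), higher is better. Item-level recoding is
instrument documentation and out of scope.

## Costing

Costs are valued in euro (index year 2021, no discounting over the 1-year
horizon) in five resource categories (intervention, mental healthcare, other
healthcare, medication, informal care) plus three productivity components
(paid-work absenteeism, unpaid-work losses, presenteeism):

* resource-use counts x unit costs from a user-supplied table
  (`unit_cost_table()`); the default table contains plausible round numbers,
  not reproductions of a national standard-cost list;
* intervention cost = attended protocol sessions x session unit cost,
  attributed evenly to follow-up periods 1-2 (the treatment phase spans
  16-24 weeks; the split is a package choice, the data do not record session
  dates);
* absenteeism: episodes valued at gender-specific wage x contracted
  hours/day; under the friction-cost approach each episode is capped at the
  friction period (12 weeks = 60 working days at a 5-day week — the
  working-day interpretation is a package choice, the friction period is
  stated in weeks). The cap applies per episode across questionnaire
  periods, with valued days attributed to consecutive quarters at 65 working
  days each; the human-capital approach removes the cap;
* presenteeism = (1 - efficiency score) x days with complaints x hours/day
  x wage;
* unpaid work at the shadow price of a legally employed cleaner.

The societal perspective sums everything; the healthcare perspective keeps
only the healthcare-tagged categories. The perspective filters the totals
but all components are always retained, so switching perspective never
requires re-costing.

## Missing data

Follow-up missingness (~31% by month 12) is handled by multiple imputation
by chained equations with predictive mean matching (PMM), which draws each
imputed value from observed donors and therefore respects the skewed,
non-negative cost distributions. Design choices, made once:

* imputation operates on the wide per-participant frame at
  period-by-category cost level and timepoint level for outcomes, so annual
  aggregation happens after imputation and skewness is preserved;
* donor pool k = 5 and 10 chained sweeps (common defaults);
* models are stratified by intervention group (a pooled option with the
  group indicator as predictor exists);
* each variable's predictors are the baseline covariates related to group,
  dropout and outcome (therapy type, age, gender, education, employment,
  baseline BDI-II, utility, functioning, pre-treatment costs), the same
  variable at other times, and the concurrent depression score;
* per-imputation random substreams are indexed by imputation number, so
  increasing m extends rather than replaces the set.

Per-imputation results are pooled by Rubin's rules (`rubin_pool()`), with
the fraction of missing information (FMI) computed from the between/within
variance decomposition. `adapt_m()` doubles m until the FMI of the monitored
headline parameters (societal cost difference and QALY difference) falls
below 5% or `m_max` is reached. The FMI estimates a property of the data
rather than of m, so with substantial missingness the 5% target may be
unreachable at any m; the loop then stops at `m_max` with a warning rather
than failing, and the achieved FMI is reported.

## Inference

Cost, QALY, PFS and SFS differences at 12 months come from linear models
with the arm indicator and therapy-type adjuster (the factorial design makes
the two factors orthogonal by construction). The BDI-II difference is the
overall arm effect over months 3-12 from a longitudinal model with
time-specific intercepts, baseline BDI-II covariate and therapy adjuster;
within-participant dependence enters through a cluster-robust (sandwich)
variance. This fixed-effects-by-time formulation targets the same estimand
as a hierarchical mixed model with patient and time levels and is used as a
transparent, dependency-light approximation to it.

Statistical uncertainty around cost-effect pairs uses nonparametric
bootstrapping of participants (all rows of a participant move together),
stratified by arm so arm sizes are preserved and cost-effect pairs are
resampled jointly. Scalar confidence intervals use the bias-corrected and
accelerated (BCa) interval; `accelerated = FALSE` switches off the
acceleration for a plain bias-corrected interval, since the two variants are
both in circulation for this analysis type. Bootstrapping happens *within*
each imputed dataset and the replicate pairs are concatenated across
imputations for the plane and the CEACs; the alternative ordering (impute
inside every resample) is out of scope. The default is B = 5000 replicates
per imputed dataset; the test-suite and the bundled acceptance run use
B = 500 to keep runtimes reasonable at unchanged structure.

## Decision-analytic outputs

The ICER is the pooled cost difference over the pooled effect difference,
carrying a quadrant label because the ratio's sign alone is ambiguous.
Quadrant proportions and CEACs orient the effect axis so that clinical
improvement is positive: BDI-II differences flip sign, QALY/PFS/SFS do not.
Pairs on a boundary count as favourable (effect >= 0) and higher-cost
(cost >= 0). The primary CEAC is parametric: per-imputation net monetary
benefit (NMB = lambda x effect - cost) and its bootstrap variance are pooled
by Rubin's rules and the probability of cost-effectiveness is the standard
normal CDF of pooled NMB over pooled SE. A cloud-counting CEAC (fraction of
replicate pairs with positive NMB) serves as a validation surface; the two
agree within 0.03 on well-behaved clouds, which the test suite checks. The
ceiling-ratio grid runs from 0 to 100 000 euro in 251 steps and always
contains the conventional reference ratios (1000 euro per scale point;
20 000, 23 000, 34 000 and 50 000 euro per QALY); only those are guaranteed
grid points, the resolution between them is a package choice.

## Sensitivity analyses

`run_sensitivity()` reruns the pipeline changing exactly one stage:

1. **healthcare** — healthcare-perspective totals;
2. **human_capital** — absenteeism valued without the friction cap;
3. **outliers** — participants generating >= 10 000 euro societal costs in
   any follow-up period have their questionnaire-based period costs recoded
   as missing before imputation. By default all four follow-up periods of a
   flagged participant are recoded (the conservative reading of a
   participant-level outlier rule); `outlier_scope = "offending"` recodes
   only the period(s) over the threshold. Intervention costs are
   administrative data and stay observed;
4. **baseline_adjust** — pre-treatment 3-month societal costs enter the cost
   model as an adjuster.

## What the synthetic generator does and does not emulate

The generator reproduces: exact requested cell sizes under stratified block
randomisation (block size 4 — a package choice, trial reports rarely state
it) allocated in a random entry order so assignment is independent of
covariates; baseline BDI-II >= 20 with severity stratification; a cohort
BDI-II course improving steeply to month 6 then plateauing, with the
twice-minus-once difference peaking at month 6, near zero at month 9 and
modest at month 12; utilities negatively correlated with concurrent
depression; overdispersed and log-normal resource use with rare very
expensive mental-healthcare episodes (psychiatric admissions) at rate 0.045
per participant in both arms; absence episodes with a lognormal tail beyond
the 60-day friction period; attended sessions near 16.5 vs 14.7 truncated
to [0, 20]; and missing-at-random dropout reaching the observed follow-up
fractions (72.5/76.5/70/69%), driven by education and baseline physical
functioning, plus 2% item-level gaps.

Two calibration choices matter for interpreting simulation results. First,
the configured annual societal cost difference (default 2000 euro) is
delivered through the intervention-cost gap plus extra mental-healthcare
contacts in the twice-weekly arm, with the per-period intensity solved from
the default unit-cost table; the analytic mean of the truncated session
distribution is used so the target is hit in expectation. Second, resource
use, presenteeism and absence are driven by the *arm-effect-free* severity
process: the configured cost and utility differences are therefore exact
structural parameters rather than emergent quantities, which is what makes
parameter-recovery tests meaningful. The price is that the generator does
not emulate cost savings mediated by faster symptom improvement — on real
data, cost and effect differences are entangled. The generator also does not
model therapy-process variables (alliance, adherence, delivery quality),
between-site heterogeneity, the second follow-up year, or arm-specific
missingness mechanisms (the trial reports none). Passing tests therefore
demonstrate correctness of the estimation machinery under a data-generating
process with the right shapes, not external validity for any particular
cohort.

## Numerical choices and degenerate inputs

* Rubin degrees of freedom use the classical (m - 1)(1 + 1/r)^2 formula and
  the FMI definition (r + 2/(df + 3))/(r + 1); B = 0 gives FMI = 0 and a
  normal reference.
* Bootstrap quantiles interpolate linearly between order statistics
  (quantile type 7); for n <= 8 an exhaustive enumeration over all n^n
  resamples is available and is what the tiny-sample tests compare against.
* A degenerate bootstrap (all replicates equal) collapses the interval to a
  point and is flagged rather than an error.
* An ICER with a zero effect difference is returned as undefined with its
  quadrant label; dominance interpretation is left to the caller.
* Collinear predictors in an imputation model are dropped with a logged
  warning; a variable with no observed values is an error.
* Observed cells are never modified by imputation, and PMM cannot produce
  values outside the observed support (in particular no negative costs).

## Problem sizes used in the shipped checks

The packaged simulation studies use n = 200 trials (the design's target
sample size): the parameter-recovery study runs 100 replicates with
adaptive m capped at 8; the acceptance run uses B = 500 bootstrap
replicates per imputed dataset with m capped at 16. These sizes were chosen
to give Monte-Carlo errors well below the effects being checked; definitive
analyses of real data should use the B = 5000 default.

## A worked run

```{r, eval = FALSE}
cfg <- trial_config(seed = 1)
conf <- cea_config(data = cfg, B = 500, m_initial = 4, m_max = 16, seed = 11)
report <- run_cea(conf)
print(report)
write_report(report, "cea-output")
plot_ceac(parametric = report$cea$QALY$ceac,
          cloud = report$cea$QALY$ceac_cloud)
```
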