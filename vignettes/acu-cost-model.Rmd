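---
title: "Costing acute care use and the budget impact of predicting it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing acute care use and the budget impact of predicting it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acucost)
```

## The problem

Patients starting systemic cancer therapy face a high risk of acute care
use (ACU): unplanned hospitalizations and emergency-department visits,
many of which are considered preventable with timely outreach. ACU
patients accrue roughly double the daily cost of non-ACU patients over the
first 180 days of therapy. A risk-prediction model deployed in the
electronic health record can flag high-risk patients for proactive triage,
but deployment, maintenance, and the nurse/advanced-practice-provider
(APP) staffing that acts on the alerts all cost money. `acucost`
implements the accounting needed to decide whether such a programme pays
for itself: Medicare-based costing of services, per-patient cost accrual,
cohort comparison, a two-equation budget-impact model, and deterministic
break-even sensitivity analysis.

## Costing services

Professional services are priced with the Medicare Physician Fee Schedule
(MPFS) three-component formula: each HCPCS/CPT code carries work,
practice-expense and malpractice relative value units (RVUs), each scaled
by its geographic practice cost index (GPCI), and the weighted sum is
converted to dollars by the annual conversion factor (CF, $/RVU). Drug
codes additionally carry the CMS payment limit of 106% of the quarterly
average sales price (ASP). The combined fee for a code at a date is the
MPFS payment plus the ASP payment for the `(year, quarter)` cell the date
falls in; codes without an ASP contribute zero for that component.

Assumptions worth stating explicitly:

* **Single locality.** One GPCI set per year — appropriate for a
  single-centre cohort. Multi-locality pricing is out of scope.
* **Annual RVUs/GPCI/CF, quarterly ASP.** This matches CMS release
  cadence; entries are stored per quarter so one `(code, year, quarter)`
  key resolves every lookup.
* **Payer perspective.** Facility fees, patient cost sharing and
  contractual adjustments are excluded; fees are CMS-allowed amounts.
* **Precision.** Money is carried at full double precision internally and
  rounded half-up to cents only at reporting boundaries, so 180-day sums
  accumulate no rounding bias. Headline savings are additionally rounded
  to the nearest $10,000, the granularity at which such projections are
  meaningfully reported.
* **Coverage gaps.** A code that cannot be priced for its quarter is a
  lookup error by default; `cost_services()` can instead drop or
  zero-cost such lines, with counts reported, since real claims mappings
  tolerate gaps.

## Cost accrual

Day 1 of a patient's window is the therapy start date; the window is days
1..180 inclusive (calendar days). Services outside the window are excluded
and counted. All lines on a day are summed — fee-for-service semantics,
with no per-encounter de-duplication, and repeated identical lines kept as
separate bills. Two summary measures follow:

* **TCPP** (total cost per patient per period): the sum of daily costs
  over the window.
* **CCPD** (cost of care per patient per day): TCPP divided by the window
  length. The divisor is the full 180 days for every included patient:
  cohort selection excludes patients who died within the window, so every
  observation period is complete.

## Cohort comparison

Group summaries use the normal-approximation interval
`mean ± 1.959964 · sd/√n`; at cohort sizes in the thousands this is
indistinguishable from a Student-t interval and is the convention that
reproduces published large-sample cost tables to the cent. Location
differences in the right-skewed cost distributions use the Mann-Whitney U
test (normal approximation with midrank-tie correction and continuity
correction — exact enumeration is reserved for test oracles at tiny n);
cumulative costs at 30/90/180 days are compared with two-tailed t tests
(Welch by default — the variant is rarely stated in published tables, and
Welch is the safer default under unequal group variances; the pooled form
is available via a flag). A summary-statistics entry point
(`welch_t_stats()`) lets published `(mean, sd, n)` tables be tested
without raw data. Categorical cohort features are compared with Pearson
chi-square tests. No multiplicity adjustment is applied: results are
reported as unadjusted p-values at α = .05.

## The budget-impact model

Let `N_total` be the annual cohort, `p_prev` the ACU prevalence, `R_sens`
and `R_spec` the prediction model's sensitivity and specificity, `p_pred`
the proportion of correctly flagged ACU events that outreach actually
prevents, and `C_acu` the mean 180-day cost of an ACU patient. Then per
year:

* expected ACU events `N_acu0 = N_total · p_prev` (a fractional
  expectation, not rounded);
* correctly flagged patients `floor(N_acu0 · R_sens)` — flags are whole
  patients, floored;
* prevented events `round(flagged · p_pred)` — rounded half-up to whole
  events.

This floor-then-half-up chain is the unique simple convention under which
the base-case parameters (2177, 0.1858, 0.84, 0.35) give 339 flagged and
119 prevented — both whole-patient quantities — and is applied
consistently everywhere the integer model is used.

Cumulative costs over `x` years:

```
C0(x) = C_acu · N_acu0 · x
C1(x) = C_deploy + C_annual·(x−1) + C_acu1·x + C_nurse·x + C_app·x
C_acu1 = C_acu · (N_acu0 − prevented)
```

The residual-cost definition `C_acu1` removes exactly the prevented
events' mean cost from the annual ACU burden. Savings in year `y` are the
increment of `C0 − C1`; ROI at year `y` is cumulative savings divided by
cumulative implementation cost (deployment + maintenance + staffing to
date). False positives (`N_total·(1−p_prev)·(1−R_spec)` per year) are
counted and reported but carry no marginal cost by default: alert triage
labour sits inside the fixed 0.25-FTE-nurse/0.5-FTE-APP staffing. An
optional per-false-positive cost `c_fp` is available for scenario
analysis. The nurse/APP split of the combined $112,765 staffing cost
defaults to 1/3 : 2/3 (mirroring the 0.25 vs 0.5 FTE weighting); only the
sum enters any computed quantity. No discounting or inflation of future
costs is applied.

Base-case defaults of `budget_params()`: `n_total = 2177`,
`p_prev = 0.1858`, `r_sens = 0.84`, `r_spec = 0.51`, `p_pred = 0.35`
(a conservative lower bound for the preventable proportion; literature
values range to ~0.67), `c_acu = 17031.92`, `c_deploy = 1e6`,
`c_annual = 2e5`, staffing `112765`.

```{r projection}
p <- budget_params()
projection(p, horizon = 6)
```

Year-1 savings are `119 × 17,031.92 − 1,000,000 − 112,765 = 914,033.48`,
i.e. $910K at $10K reporting granularity, and the programme breaks even in
year 1. Note that multi-year cumulative figures published alongside such
models are not always derivable from their stated yearly parameters; this
package reports only the internally consistent projection implied by the
inputs above.

## Break-even sensitivity

Savings enter linearly in each of `R_sens`, `p_prev`, `N_total`, `p_pred`
(modulo the integer rounding steps), so one-way analysis is sufficient and
deterministic. `one_way_sweep()` evaluates the integer-rounded model on a
grid; `break_even_threshold()` bisects the *continuous relaxation*
(prevented events `= N_total·p_prev·R_sens·p_pred`, no flooring) for the
smallest parameter value with non-negative cumulative savings at the
horizon. Two views are reported because the integer model is a step
function: the continuous root and the rounded sweep can differ by up to
one grid step, and the relaxation admits a closed form, e.g. for `p_pred`
at horizon `H`:

```
p_pred* = (C_deploy + C_annual·(H−1) + staffing·H) / (H · N_acu0 · R_sens · C_acu)
```

Bisection runs to a parameter tolerance of 1e-8 (the function is monotone,
so bracketing is trivial; a preconditioned "no break-even in range" result
is returned when savings never cross zero, e.g. with `c_acu = 0`). Fixed
costs amortise with the horizon, so 1-year thresholds always exceed
6-year thresholds. `break_even_year()` scans the projection for the first
year with non-negative cumulative savings.

```{r breakeven}
break_even_threshold(p, "p_pred", horizon = 6)
break_even_year(p)
```

## What the synthetic data emulate — and what they do not

`gen_synthetic_study()` exists so that every module is exercisable
end-to-end without claims or EHR access. Under one seed it deterministically
produces a fee schedule, a cohort with service streams, and risk flags.
Design choices, fixed once:

* **Fee schedule** (`n_codes = 120`, 20% drug codes): lognormal RVU
  components (costs and service weights are positive and right-skewed),
  GPCI near 1, CF at 34.6062 $/RVU (the recent MPFS range), quarterly ASP
  drift of ~2%. Two calendar years are generated so windows starting late
  in the start year stay priceable.
* **Group totals**: each patient's 180-day total is drawn from a lognormal
  moment-matched to the group target mean/SD (defaults $17,031.92 /
  SD $13,056.63 for ACU; $9,591.06 / SD $10,785.83 for non-ACU; SD > mean/2
  rules out symmetric-normal costs). Prevalence is Bernoulli at 0.1858.
* **Daily shape**: an exponential-decay mean profile with a 60-day time
  constant — front-loaded therapy costs that flatten, as cumulative cost
  curves of such cohorts do — plus, for ACU patients, a 7-day boxcar
  "episode" burst holding 35% of their total at a random onset day, which
  makes the ACU group's mean cumulative curve dominate from early in the
  window.
* **Realisation as claims**: daily targets are converted to integer-unit
  service lines priced against the generated schedule, with *stochastic
  rounding* of units (`floor(target/fee + U)`, `U ~ Uniform(0,1)`), which
  is unbiased for the target regardless of the fee drawn. Realisation
  noise inflates group SDs by roughly 1% and leaves means unbiased.
* **Flags**: Bernoulli(`r_sens`) for true ACU patients,
  Bernoulli(`1 − r_spec`) otherwise, independent across patients.
* **Features**: categoricals sampled conditionally on ACU status (stage,
  tumour type, insurance) with ACU-enriched directions, so chi-square
  comparisons have genuine signal.

What this does **not** emulate: real HCPCS semantics or service-mix
composition, inter-day cost correlation beyond the fixed profile,
censoring/death processes, out-of-network care, or any relationship
between the features and costs. Passing recovery tests on synthetic data
therefore demonstrates that the *accounting machinery* is correct — fees
compose, accrual conserves cost, statistics recover configured
parameters — not that the generator reproduces real claims.

Recovery at the default cohort size of 20,000 patients (the scale used in
the package's acceptance tests) brings group means within ~1% of targets
and empirical flag sensitivity/specificity within 3 binomial standard
errors; unit tests use cohorts of a few hundred to a few thousand patients
to keep the default test run in tens of seconds.

## Numerical and degenerate-input conventions

* Half-up rounding (`floor(x + 0.5)` with a 1e-9 representation guard) for
  whole events and cents; base R's banker's rounding would turn 118.65
  into 118.
* `floor` of event counts uses the same 1e-9 guard so decimal products
  that are exact on paper do not floor one unit low.
* Degenerate inputs error early with named keys: duplicate
  `(code, year, quarter)`, a year without GPCI/CF, units < 1, empty
  samples, `n < 2` summaries, contingency tables with a zero expected
  cell (with advice to merge categories), checkpoints outside the window,
  horizons < 1.
* Lookup errors distinguish "code never seen" from "code missing for this
  quarter".
* The fee-schedule CSV writer emits doubles at 17 significant digits, so a
  write/parse round trip reproduces every fee bit-identically.

## Limitations

The budget model is an expectation model: it carries fractional expected
events through cost products and rounds only where whole patients are
counted, ignores year-to-year stochastic variation in event counts, and
values prevention only in averted mean ACU cost — no health outcomes,
QALYs, or heterogeneous per-event costs. One-way sensitivity cannot
expose interactions between parameters (they only enter savings as a
product, so thresholds for one parameter scale inversely with the
others). Medicare allowed amounts understate or overstate costs under
other payers' contracts, and single-locality GPCI limits geographic
generalisation.
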