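---
title: "A Markov cost-utility model for definitive treatment of low-risk prostate cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-utility model for definitive treatment of low-risk prostate cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostcea)
```

## The decision problem

Men diagnosed with localized low-risk prostate cancer who opt for (or
must move to) definitive treatment face a choice between external-beam
radiotherapy and surgery. `prostcea` implements a cost-utility
comparison of the two strategies most commonly weighed in Japanese
practice: moderately hypofractionated intensity-modulated radiotherapy
delivered in 20 fractions (IMRT-20, with a 38-fraction conventional
variant as a scenario) and robot-assisted radical prostatectomy (RARP).
The perspective is the healthcare payer: only direct medical costs under
the national fee schedule enter the model, in JPY (a 152 JPY/USD
conversion is provided for display). Effectiveness is measured in
quality-adjusted life-years (QALYs); strategies are compared by the
incremental cost-effectiveness ratio (ICER) and the incremental net
monetary benefit (INMB) at a willingness-to-pay (WTP) threshold of
5,000,000 JPY/QALY.

## Model structure

A cohort of 65-year-old men is propagated through five mutually
exclusive health states in monthly cycles over a 20-year horizon
(240 cycles):

* `INITIAL_TREATMENT` — the treatment cycle itself (cycle 0);
* `PSA_CONTROLLED` — biochemical control;
* `PSA_FAILURE` — biochemical recurrence, a one-cycle *tunnel* state;
* `ADT` — uncontrolled disease on androgen deprivation therapy;
* `DEAD` — absorbing, all-cause mortality.

On leaving the initial state, 90% of patients achieve PSA control and
10% fail, in both arms. The arms then diverge in the failure tunnel:
after RARP, salvage radiotherapy to the prostate bed restores control in
50% of failures, the rest moving to lifelong ADT; after IMRT, failures
move directly to ADT with no salvage option. Treating `PSA_FAILURE` as a
one-cycle tunnel keeps the salvage decision, and its one-time cost,
attached to the inflow into the state. A configurable monthly
late-failure hazard out of `PSA_CONTROLLED` exists but defaults to 0:
the base case models only the one-time 90/10 split, and we deliberately
do not invent an ongoing relapse rate.

Death competes proportionally with the clinical transitions: every
clinical probability in a cycle is scaled by `1 - q_m`, where `q_m` is
the monthly all-cause death probability at the cohort's current age
(ages advance one year every 12 cycles; the annual probability `q_x` is
converted by `1 - (1 - q_x)^(1/12)`). This is the standard cohort-model
convention when no cause-specific ordering is known. No excess
cancer-specific mortality is applied: over a 20-year horizon, low-risk
disease managed with curative intent is modeled with background
mortality only. Occupancy is counted at cycle start and no half-cycle
correction is applied (`settings$half_cycle_correction` is reserved as a
switch); with monthly cycles the correction is at most half a month of
accrual and is far below the other structural uncertainties.

## Parameters

All inputs live in one validated container (`default_parameters()`),
addressable by dotted paths and overridable from a YAML config
(`load_config()`). The headline values:

| Group | Parameter | Default |
|---|---|---|
| Clinical | PSA control, either arm | 0.90 |
| | Salvage success (RARP) | 0.50 |
| | AE prevalence, IMRT: urinary / sexual / GI | 0.031 / 0.389 / 0.098 |
| | AE prevalence, RARP: urinary / sexual | 0.098 / 0.540 |
| | One-year cure, RARP: urinary / sexual | 0.645 / 0.890 |
| Costs (JPY) | IMRT-20 / IMRT-38 course | 1,076,180 / 1,445,580 |
| | RARP surgery + hospitalization + anesthesia | 952,880 + 260,880 + 100,000 |
| | Salvage radiotherapy course | 1,265,110 |
| | ADT, annual | 224,690 |
| Utilities | Base | 0.90 |
| | Decrement: PSA failure / urinary / sexual | 0.17 / 0.17 / 0.11 |
| Settings | Discount, horizon, start age | 2%/y, 20 y, 65 |
| | WTP, exchange rate | 5,000,000 JPY/QALY, 152 JPY/USD |

Two quantities that the fee schedule and trial literature do not pin
down default to zero and are exposed in the config: the per-month
adverse-event management costs (`costs$ae_management`) and the
gastrointestinal utility decrement (`utilities$dec_gi`). Inventing
values for them would fabricate data; the consequences of this choice
are discussed under *Limitations*.

## Adverse-event burden and utilities

The model carries no explicit adverse-event states. Instead each event
contributes an expected-value decrement: prevalence among the alive
times the event's utility decrement, subtracted additively from the base
utility (a multiplicative combination is available via
`settings$multiplicative_utilities`). Patients in `PSA_FAILURE` or `ADT`
additionally carry the 0.17 disease-state decrement — applied in both
states, since the tunnel cycle is the salvage month and plainly not a
period of full health. Utilities are floored at 0 and the sexual
decrement is scaled by `utilities$sexual_weight`, the lever of the
preference-sensitivity sweep.

The prevalence *schedules* must reconcile two published facts: one-year
prevalences for both arms, and one-year *cure rates* after surgery
(urinary 64.5%, sexual 89.0%) reflecting recovery of function during the
first postoperative year. We read the cure rate as the fraction of the
initially affected complement that recovers within the year, giving a
reconstructed month-1 prevalence after RARP of
`p_1yr + cure * (1 - p_1yr)` (sexual: 0.540 + 0.890 × 0.460 = 0.9494),
declining linearly to the one-year value at month 12 and constant
thereafter. IMRT arms hold their one-year value from month 1; the
gastrointestinal burden stops after month 36 (its prevalence is a
three-year figure), urinary and sexual burdens persist. All durations
sit in `settings$ae_duration_months`. No burden applies in cycle 0. This
wiring keeps the RARP sexual burden at or above the IMRT burden in every
cycle, which is what makes the INMB increase in the sexual-disutility
weight.

## Economics

Cycle 0 bills the full upfront treatment cost (IMRT course, or surgery +
hospitalization + anesthesia = 1,313,760 JPY for RARP). Each cycle then
accrues one-twelfth of the annual ADT cost per unit of ADT occupancy,
and — in the RARP arm — one salvage course per new entrant into the
failure tunnel. Routine follow-up and PSA monitoring are assumed
identical across arms and are omitted, as are capital expenditures.
Costs and QALYs are discounted at `d(t) = 1.02^(-t/12)` and accumulated
over cycles 0–239; money is carried at full precision and rounded only
for display.

`compute_icer()` returns dominance labels (`DOMINANT`, `DOMINATED`,
`UNDEFINED`) instead of dividing by non-positive QALY differences;
`compute_inmb()` (`ΔQALY × WTP − ΔCost`) is defined for every sign
combination, which is why the disutility sweep reports INMB rather than
ICERs.

## Mortality input

No Japanese national life table ships with the package (the deliverable
is self-contained); `generate_life_table()` synthesizes one from the
Gompertz–Makeham law `q(x) = 1 - exp(-(a + b e^{cx}))`, the standard
two-parameter description of adult mortality. The scale `b` is
calibrated by root-finding so that the discrete life expectancy at 65
hits a target of 19.4 years — typical of contemporary Japanese men — to
within 0.05 years; the target, like every other constant, is a config
number, not hard-coded truth. A real national table can be supplied as a
two-column `age,qx` CSV via `read_life_table()`, which validates
coverage of ages 65–85 and warns on non-monotone entries. A synthetic
table reproduces the *level* of background mortality but not the exact
age profile of a national table, so absolute QALY totals shift by a few
tenths with the mortality source; incremental results barely move, since
both arms face identical mortality.

## Sensitivity analysis

**One-way (tornado).** `default_ranges()` varies each parameter by
±25% of base (probabilities clipped to [0, 1]), except PSA control which
uses the explicit plausible range 0.80–0.95. `one_way_dsa()` rebuilds
both arms at each extreme and records the INMB; entries are sorted by
spread. Two structural identities double as oracles: a cycle-0 cost
moved by X shifts the INMB by exactly −X (so its spread equals its range
width), and the IMRT-38/IMRT-20 pair differ by exactly their price gap.
Under the defaults the initial PSA control probability dominates the
tornado and the INMB stays positive across every tested range.

**Probabilistic.** `run_prsa()` samples all parameters independently —
beta for probabilities and utilities, gamma for costs, log-normal
available for relative-risk-type inputs (unused by default, the base
model carries none) — each parameterized by matching mean and standard
deviation (method of moments). Published standard deviations are not
available, so every sampled parameter defaults to sd = 25% of its mean,
overridable per parameter; sampled utility decrements are rescaled so
their sum never exceeds the sampled base utility. Because the input
standard deviations are a package choice, the probability
cost-effective is a plausibility-scale result, not a reproduction of any
published figure. The default run is 10,000 iterations (Monte-Carlo
standard error on a proportion ≤ 0.005), seconds to minutes of compute;
`analysis/03_prsa.R` accepts a larger count for million-scale runs.
`ceac()` is a pure function of the iteration records, so the
acceptability curve can be recomputed bit-identically from the exported
CSV.

## Validation strategy

The cohort engine is validated by independent routes rather than by
re-asserting its own output:

* every generated transition matrix is row-stochastic to 1e-12 and every
  trace conserves mass to 1e-10 over randomized valid parameter sets;
* with zero mortality the occupancies reach closed-form limits
  (0.90/0.10 controlled/ADT for IMRT, 0.95/0.05 for RARP) exactly;
* the loop-based propagation is checked cycle-by-cycle against explicit
  row-by-matrix multiplication;
* `microsim_oracle()` re-simulates individual patients by categorical
  draws, sharing only the reward functions with the cohort engine; the
  test suite requires agreement within three standard errors at
  n = 100,000 individuals per arm (about 4 s each), and at n = 30,000
  for randomized parameter sets;
* the INMB's affinity in the sexual-disutility weight is checked against
  the model-free slope `WTP × dec_sexual × Δ(discounted sexual-prevalence
  exposure)` to 1e-6 relative.

## Known limitations

* The model intentionally reproduces a *structure*, not any particular
  published total: absolute discounted QALYs and costs depend on the
  mortality table, the adverse-event duration wiring and the
  management-cost assumptions, of which only the structure is public.
* With adverse-event management costs and the gastrointestinal decrement
  at their default 0, IMRT-20 is both cheaper and more effective than
  RARP at every sexual-disutility weight, so the weight sweep never
  changes sign: the INMB at weight 0 is already positive, because the
  first-year urinary recovery ramp after surgery outweighs the salvage
  pathway's benefit. A configuration in which surgery management costs
  or a GI disutility penalize IMRT shifts the weight-0 INMB negative and
  produces an interior crossing; the crossing machinery is exercised on
  such a configuration in the test suite.
* Parameters are sampled independently in the probabilistic analysis; no
  correlation structure is imposed.
* Active surveillance, brachytherapy, stereotactic radiotherapy, proton
  therapy and androgen-receptor signalling inhibitors are out of scope,
  as are societal costs and capital expenditure.

## A worked run

```{r base-case}
params <- default_parameters()
life_table <- generate_life_table()
report <- run_base_case(params, life_table)
report
```

```{r sweep}
sw <- sweep_sexual_disutility(params, life_table = life_table)
sw$rows[c(1, 6, 11), ]
```
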