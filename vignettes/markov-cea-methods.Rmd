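---
title: "Methods: a Markov cohort model for the cost-effectiveness of person-centred ACS care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for the cost-effectiveness of person-centred ACS care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acscea)
```

`acscea` re-implements a health-economic simulation model that projects the
outcomes of a Swedish randomized trial of person-centred care (PCC) for
patients under 65 hospitalised with acute coronary syndrome (ACS), comparing
PCC with usual care over 2-year and 5-year horizons. This vignette is the
package's account of the model, its conventions, and the choices made where
the published description left the design open.

## The cohort model

Clinically the model distinguishes remission, relapse, and death. Because
relapse risks and costs depend on how many relapses a patient has had, the
engine expands this to seven states that encode the relapse count —
initial event, remission 1, relapse 1, remission 2, relapse 2, remission 3,
dead — which makes the process Markov. A relapse (a new ACS
hospitalisation) lasts exactly one monthly cycle, after which the cohort
moves to the next remission or dies; after the second relapse, patients
remain in the third remission until death. The cycle length is one month and
the full horizon is 60 cycles (24 for the short perspective).

Transition risks are monthly probabilities. For the first 24 cycles the
relapse risks are arm-specific (estimated from trial-linked register data in
the original analysis); from cycle 24 onward all risks are
treatment-independent literature values. Mortality risks depend on the
health state but not on the arm. `transition_matrix()` builds the
row-stochastic matrix for any cycle; `run_cohort()` propagates the occupancy
distribution and records per-cycle reward accruals; `accumulate_outcomes()`
discounts and sums them.

The cohort starts in the first remission by default. The initial ACS
hospitalisation is common to both arms, so it cancels from every increment;
a flag (`settings$include_initial_event_month`) starts the cohort in an
initial-event state costed and weighted as a relapse month for users who
want absolute (non-incremental) outputs to include it.

## Reward accrual conventions

Three accounting conventions matter, and the published base-case numbers
identify them fairly sharply:

* **Timing.** Rewards accrue on start-of-cycle occupancy, without
  half-cycle correction (`settings$half_cycle_correction` enables the
  averaged alternative). Deaths during a cycle therefore accrue that cycle's
  rewards through their start-of-cycle state.
* **Cycle-length factor.** Quality-adjusted life years accrue as annual
  utility weight × 1/12 per cycle. The published cost increments are
  reproduced (to within a few per cent) only when the *same* 1/12
  cycle-length factor is applied to every cost stream, i.e. each cycle
  accrues one-twelfth of the tabulated unit cost. The engine adopts this
  annualised accrual as its default (`settings$cost_accrual = "annualised"`);
  `"per_cycle"` accrues the full unit value per month for users who read the
  unit costs as literal per-month amounts. All incremental results in this
  package's documentation use the default.
* **Sick-leave scale.** The monthly sick-leave indirect cost rows enter the
  published incremental results at one-thousandth of their face value (the
  published sick-leave increments are a few thousand SEK per 1000 patients,
  where face-value accrual would give a few million; the published
  sick-leave threshold value, around 340,000 SEK against a base of 8,250, is
  likewise only consistent with the reduced scale). The engine exposes this
  as `settings$sick_leave_scale` (default `1e-3`) and documents it as a
  reproduction convention: set it to 1 for face-value accrual, in which case
  sick-leave differences dominate every perspective that includes them.

Mortality-related productivity losses are valued by the human-capital
method: a death during cycle `m` loses the average gross monthly income
(46,400 SEK, labour taxes included) for every month from `m + 1` to the end
of the horizon, discounted at the cost rate and carrying the same
cycle-length factor as the other cost streams. Productivity losses are
counted only within the modelled horizon, which makes the incremental
results conservative (the comparator arm loses more life-months).

Costs and effects are discounted at 3% per year in the base case,
as `(1 + r)^(-m/12)` for cycle `m`; the deterministic sensitivity analysis
re-runs every combination of 0% and 5% for effects and costs.

## Cost-effectiveness comparison

`compare_arms()` runs both arms under identical settings and reports
increments (PCC minus usual care) scaled to 1000 patients under three
costing perspectives: direct healthcare costs only; direct plus sick-leave
indirect costs; and the societal perspective adding mortality-related
productivity losses. ICERs carry an explicit quadrant label because the
base case is dominance (PCC is both cheaper and more effective), where a
raw ratio is not a decision quantity. All internal decision rules — the
threshold search and the acceptability curve — therefore work on net
monetary benefit, `NMB = λ·ΔE − ΔC`, which has the correct sign in every
quadrant.

```{r}
res <- compare_arms(default_parameters())
tidy(res)
```

## Deterministic sensitivity analysis

`one_way_sweep()` varies one intervention-arm parameter at a time;
`threshold_search()` finds, by bisection on the per-patient NMB at a
willingness-to-pay of 500,000 SEK/QALY, the parameter value at which PCC
stops being cost-effective. Bisection was chosen because the NMB is
continuous and monotone in each swept parameter but not analytically
differentiable through the cohort recursion; the search stops when the
per-patient NMB is below 1e-6 SEK or the bracket is exhausted
(relative width 1e-10), and is fully deterministic.

Two sweep-address choices were genuinely open:

* The threshold analyses default to the 5-year horizon and the societal
  perspective; the published threshold values are reproduced under exactly
  that combination.
* The published remission-cost and relapse-cost thresholds are reproduced
  (to within a few per cent) when the sweep varies the *first* remission or
  relapse cost row only; sweeping all remission rows (or both relapse rows)
  together moves the thresholds roughly 5–10% lower. The package therefore
  sweeps the single state-1 row for those two analyses and keeps the
  block-wide sweep available through the address aliases
  `pcc.costs.remission` and `pcc.costs.relapse`.

## Probabilistic sensitivity analysis

Risks and utility weights are drawn from beta distributions, costs from
log-normal distributions, each moment-matched so that the base-case value is
the arithmetic mean. The dispersion rule sets the standard deviation to 20%
of the mean (`psa_distributions(rule = "sd_fraction_of_mean")`). The
alternative literal reading — variance equal to 20% of the mean — is
implemented but infeasible for the remission utility of 0.82 (it violates
the beta constraint `v < m(1−m)`), so the SD rule, which keeps every
tabulated row valid, is the default; infeasible combinations raise errors
rather than being clipped.

Parameters that the base case shares between arms (mortality risks, the
treatment-independent 5-year risks, utility weights) are drawn once per
replicate and applied to both arms, inducing between-arm correlation that
mirrors the shared cells; arm-specific parameters (2-year relapse risks,
costs) are drawn independently per arm. Draws are replicate-major and
spec-ordered, so `run_psa()` is bit-reproducible for a given seed (default
1000 draws, seed 1234).

Two constructions of the "probability of cost-effectiveness" are provided,
and they differ materially here. The quadrant-safe construction counts
replicates with positive NMB. The construction used by the published
acceptability curves counts replicates whose *raw ratio* ΔC/ΔE falls below
the threshold; replicates in the dominated quadrant (less effective, more
costly) have negative ratios and are counted as "cost-effective" by that
ordering. Because the arm-specific relapse-risk draws make the sign of ΔE
genuinely uncertain (roughly a third of replicates are dominated at these
dispersions), the NMB-based probability is bounded by P(ΔE > 0) and sits
well below the ratio-ordering share. `ceac()` and `prob_cost_effective()`
default to the NMB construction and expose
`method = "icer_ordering"` for comparison with published curves; the
acceptance checks compare the ratio-ordering share against the published
likelihood ranges, since that is the quantity those ranges describe.

## Parameter estimation from register-like records

The estimators implement the derivation procedures of the original
analysis on patient-level records:

* 2-year relapse risks: the proportion of patients with a qualifying event
  (first or second relapse) within 24 months, converted to a monthly
  probability. The conversion convention is selectable:
  constant hazard, `1 − (1 − T)^(1/24)` (default), or linear `T/24`; the
  method used is recorded in the fitted object's metadata.
* Relapse cost: total inpatient ACS event costs divided by the number of
  events.
* Remission cost: total non-inpatient costs divided by remission
  patient-months (a relapse occupies one month; follow-up is truncated at
  death).
* Sick-leave cost: each reimbursed spell contributes its reimbursed days
  plus 14 (the qualifying period the register does not reimburse), valued
  at the daily production value (gross monthly income over 20 working
  days); permanent sick leave contributes a full wage per month from its
  start unless it predates the initial event. All absenteeism is attributed
  to the ACS condition.

One estimand subtlety matters for validation: the 2-year event proportion
is a *crude* cumulative incidence, with death competing. In the presence of
mortality it therefore under-states the latent monthly transition risk by
roughly the probability of dying first (about 10% relatively at these
rates). The recovery tests account for this by checking the estimator
against its closed-form estimand on realistic cohorts, and against the
latent risk on cohorts simulated without competing mortality, where the two
coincide. Users fitting the model to real register data inherit the same
convention the original analysis used.

## The synthetic-data generator

`simulate_patients()` emulates RCT-linked register data: monthly state
paths simulated from ground-truth parameters (the same transition rules as
the cohort engine, which lets the path simulator double as an independent
microsimulation cross-check of the deterministic recursion), log-normal
inpatient costs around the arm's relapse cost (CV 0.5), log-normal
non-inpatient monthly costs around the remission cost (CV 0.5), and
Poisson-distributed reimbursed sick-leave spells with geometric day counts
(mean 30 reimbursed days). The spell rate is calibrated per arm so the
expected human-capital cost per patient-month equals the arm's tabulated
sick-leave cost, making the generator-estimator pair self-consistent.
`trial_cohort()` produces a fixed 117-patient cohort (59 usual care, 58
PCC, 24 months) as a smoke fixture matching the size of the under-65 trial
population.

What the generator does *not* emulate: diagnosis codes and DRG-weighted
visit costing (costs are drawn directly around state means), informative
censoring (follow-up is complete until death), seasonal or calendar-time
structure, and any correlation between a patient's cost level and their
event history. Passing recovery tests therefore show that the estimators
implement their definitions correctly on data with the assumed structure,
not that the assumed structure captures everything in real registers.

## Problem sizes and numerical choices

The test-suite problem sizes are chosen to keep Monte Carlo error well
below the tested tolerances: microsimulation cross-checks at one million
patients (maximum occupancy deviation within three binomial standard
errors), sampler moment recovery at 100,000 draws (within 1%), estimator
recovery at 10,000 patients per arm (within three standard errors),
probabilistic sensitivity analysis at the published 1000 draws. State
occupancy is conserved to 1e-12 per cycle; degenerate inputs (zero-width
threshold brackets, empty arms, total risk of 1 under constant hazard,
infeasible beta variances) raise informative errors rather than being
clipped or silently adjusted.

## Known limitations

* The two reproduction conventions (annualised cost accrual, reduced
  sick-leave scale) are faithful to the published accounting rather than to
  a textbook cohort-model formulation; both are settings, and switching
  them changes absolute and incremental costs by an order of magnitude.
* Quality-of-life weights are state-dependent but arm- and time-independent;
  no age structure, comorbidity, or post-horizon extrapolation is modelled.
* The sick-leave stream applies uniformly to all alive patient-months,
  arm-specifically; absenteeism is not a model state.
* ICER-based acceptability shares (the published construction) should not
  be used for decisions when draws can be dominated; use the NMB
  construction.
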