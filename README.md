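# acscea

Markov cohort cost-effectiveness modelling of person-centred care for
patients with acute coronary syndrome (ACS).

Person-centred care (PCC) — care co-produced with the patient as an active
partner — has shown clinical benefit for working-age ACS patients in a
Swedish randomized trial, but trials end after one or two years while
decision-makers need longer horizons. `acscea` implements the
health-economic simulation model used to project those trial outcomes to a
five-year perspective: a monthly-cycle Markov cohort model whose three
clinical states (remission, relapse, dead) are expanded into a seven-state
space that tracks the relapse count (initial event, remissions 1–3,
relapses 1–2, dead). For each arm the model accrues discounted
quality-adjusted life years (QALYs), life years, state-related healthcare
costs, sick-leave indirect costs, and mortality-related productivity losses
valued by the human-capital method.

The core quantities are the incremental comparison of PCC against usual
care,

- ICER = ΔC / ΔE, reported with an explicit dominance quadrant,
- NMB(λ) = λ·ΔE − ΔC, the net monetary benefit at willingness-to-pay λ
  (500,000 SEK/QALY by default),

under three costing perspectives (direct costs only; plus sick-leave
indirect costs; plus mortality-related productivity losses). Around the
base case the package provides deterministic sensitivity analysis
(discount-rate scenarios, one-way sweeps, bisection threshold search on the
NMB), probabilistic sensitivity analysis (moment-matched beta/log-normal
parameter distributions, seeded Monte Carlo, cost-effectiveness plane and
acceptability curve), estimators that derive the model parameters from
patient-level register-like records, and a synthetic register-data
generator that doubles as an individual-level microsimulation cross-check
of the cohort engine.

## Worked example

```r
library(acscea)

params <- default_parameters()   # published base-case parameter set, 5-year horizon
res <- compare_arms(params)
res
#> <acs_cea> horizon 60 months, per 1,000 patients, WTP 5e+05 SEK/QALY
#>   incremental QALYs 2.60, life years 2.65
#>   direct_only            delta cost     -88779  ICER     -34174  (dominant)
#>   direct_plus_sick_leave delta cost     -92857  ICER     -35744  (dominant)
#>   societal               delta cost    -216019  ICER     -83153  (dominant)
```

Per 1000 patients over five years, PCC gains about 2.6 QALYs and saves
about 216,000 SEK from the societal perspective — it *dominates* usual care
(cheaper and more effective), so the negative ICER of about −83,000
SEK/QALY is a label of dominance, not a price. `tidy(res)` returns the
perspective table as a tibble and `glance(res)` a one-row summary.

How far can the intervention arm's first-relapse risk rise before PCC stops
being cost-effective at 500,000 SEK/QALY?

```r
threshold_search(params, "pcc.risks_2y.relapse1", bracket = c(0.0093, 0.2))
#> # A tibble: 1 × 9
#>   address               base_value threshold    wtp horizon_months perspective converged
#>   <chr>                      <dbl>     <dbl>  <dbl>          <dbl> <chr>       <lgl>
#> 1 pcc.risks_2y.relapse1     0.0093    0.0113  5e+05             60 societal    TRUE
```

The monthly risk may rise from 0.93% to about 1.13% per month. Other
entry points: `run_psa()` / `ceac()` / `autoplot()` for the probabilistic
analysis, `discount_scenarios()` and `one_way_sweep()` for deterministic
sensitivity, `simulate_patients()` and `fit_parameters()` for the
register-data estimation pipeline, and a command-line wrapper in
`inst/cli/acscea.R` (subcommands `run`, `dsa`, `psa`, `estimate`, `synth`).

The methods vignette (`vignettes/markov-cea-methods.Rmd`) documents the
model assumptions, the reward-accrual conventions under which the published
accounting is reproduced, and the design decisions taken where the
published description was open.

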