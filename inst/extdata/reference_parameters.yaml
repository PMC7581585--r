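usual_care:
  risks_2y:
    relapse1: 0.0115
    relapse2: 0.0035
    death_after_relapse1: 0.0248
    death_after_relapse2: 0.0248
    death_after_remission1: 0.0106
    death_after_remission2: 0.0115
    death_after_remission3: 0.0115
  risks_5y:
    relapse1: 0.0062
    relapse2: 0.0062
    death_after_relapse1: 0.0037
    death_after_relapse2: 0.0037
    death_after_remission1: 0.0022
    death_after_remission2: 0.0022
    death_after_remission3: 0.0022
  costs:
    relapse1_cost: 45307.0
    relapse2_cost: 45307.0
    remission1_cost: 2176.0
    remission2_cost: 2176.0
    remission3_cost: 2176.0
    sick_leave_monthly: 9349.0
  utilities:
    relapse: 0.67
    remission: 0.82
  delivery_cost_fixed: 0.0
  delivery_cost_per_month: 0.0
pcc:
  risks_2y:
    relapse1: 0.0093
    relapse2: 0.0056
    death_after_relapse1: 0.0248
    death_after_relapse2: 0.0248
    death_after_remission1: 0.0106
    death_after_remission2: 0.0115
    death_after_remission3: 0.0115
  risks_5y:
    relapse1: 0.0062
    relapse2: 0.0062
    death_after_relapse1: 0.0037
    death_after_relapse2: 0.0037
    death_after_remission1: 0.0022
    death_after_remission2: 0.0022
    death_after_remission3: 0.0022
  costs:
    relapse1_cost: 39824.0
    relapse2_cost: 39824.0
    remission1_cost: 2223.0
    remission2_cost: 2223.0
    remission3_cost: 2223.0
    sick_leave_monthly: 8250.0
  utilities:
    relapse: 0.67
    remission: 0.82
  delivery_cost_fixed: 0.0
  delivery_cost_per_month: 0.0
settings:
  discount_rate_costs: 0.03
  discount_rate_effects: 0.03
  gross_monthly_income: 46400.0
  working_days_per_month: 20.0
  wtp_threshold: 500000.0
  horizon_months: 60.0
  switch_month: 24.0
  cohort_scale: 1000.0
  include_initial_event_month: no
  half_cycle_correction: no
  cost_accrual: annualised
  sick_leave_scale: 0.001
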