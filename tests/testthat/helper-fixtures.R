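# Shared test fixtures, built in code.

# Parameters with every transition risk zeroed: the cohort never leaves the
# first remission, which gives closed-form accruals.
zero_risk_params <- function(horizon = 24) {
  p <- default_parameters()
  for (arm in c("usual_care", "pcc")) {
    for (block in c("risks_2y", "risks_5y")) {
      for (f in names(p[[arm]][[block]])) {
        p <- param_set(p, paste(arm, block, f, sep = "."), 0)
      }
    }
  }
  param_set(p, "settings.horizon_months", horizon)
}

no_discount <- function(p) {
  p <- param_set(p, "settings.discount_rate_costs", 0)
  param_set(p, "settings.discount_rate_effects", 0)
}

# A tiny hand-built patient record table for estimator arithmetic.
hand_records <- function() {
  tibble::tibble(
    patient_id = paste0("p", 1:4),
    arm = c("usual_care", "usual_care", "pcc", "pcc"),
    follow_up_months = 24L,
    relapse_months = list(c(5L), integer(0), c(3L, 9L), integer(0)),
    inpatient_event_costs = list(40000, numeric(0), c(50000, 30000), numeric(0)),
    non_inpatient_costs = list(rep(200, 23), rep(100, 24), rep(300, 10), rep(50, 24)),
    sick_leave_spells = list(c(10L), integer(0), c(20L, 6L), integer(0)),
    death_month = c(NA_integer_, NA_integer_, 12L, NA_integer_),
    permanent_sick_leave_start = NA_integer_,
    pre_existing_permanent_sick_leave = FALSE
  )
}

# Printed reference results the model is expected to approximate (per 1000
# patients; QALY increments, total-cost increments, ICERs by perspective).
published_base_case <- list(
  qalys_2y = 1.04, qalys_5y = 2.70,
  total_cost_2y = -158792, total_cost_5y = -222314,
  icer_total_2y = -152764, icer_total_5y = -82292,
  icer_direct_sick_5y = -34604, icer_direct_5y = -32688
)
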