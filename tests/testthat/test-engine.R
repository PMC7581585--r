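test_that("transition matrices are row-stochastic and match the published risks", {
  p <- default_parameters()

  P <- transition_matrix(p$usual_care, p$settings, month = 3)
  expect_equal(P["relapse_1", "dead"], 0.0248)
  expect_equal(P["relapse_1", "remission_2"], 0.9752)
  expect_equal(sum(P["relapse_1", ] != 0), 2) # no self-loop in relapse
  expect_equal(P["dead", "dead"], 1)

  # beyond the switch month both arms use the treatment-independent risks
  for (arm in c("usual_care", "pcc")) {
    P5 <- transition_matrix(p[[arm]], p$settings, month = 30)
    expect_equal(P5["remission_1", "relapse_1"], 0.0062)
    expect_equal(P5["remission_3", "dead"], 0.0022)
  }

  # property: rows sum to one for randomly drawn valid risk sets
  set.seed(42)
  for (i in 1:25) {
    q <- default_parameters()
    for (f in names(q$pcc$risks_2y)) {
      q <- param_set(q, paste0("pcc.risks_2y.", f), runif(1, 0, 0.3), validate = FALSE)
    }
    Pr <- transition_matrix(q$pcc, q$settings, month = 0)
    expect_equal(unname(rowSums(Pr)), rep(1, 7), tolerance = 1e-14)
    expect_true(all(Pr >= 0))
  }

  # an infeasible remission row is rejected
  q <- param_set(default_parameters(), "pcc.risks_2y.relapse1", 0.999, validate = FALSE)
  expect_error(transition_matrix(q$pcc, q$settings, 0), "exceeds 1")
})

test_that("discount factors follow (1+r)^(-m/12)", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03)
  expect_equal(discount_factor(0:60, 0), rep(1, 61))
  expect_equal(discount_factor(30, 0.05), 1.05^(-2.5))
})

test_that("a zero-risk cohort stays in remission with closed-form accruals", {
  p <- no_discount(zero_risk_params(horizon = 24))
  trace <- run_cohort(p$usual_care, p$settings)
  expect_equal(nrow(trace), 24)
  expect_equal(trace$remission_1, rep(1, 24))
  expect_equal(trace$dead, rep(0, 24))
  expect_equal(sum(trace$new_deaths), 0)

  out <- accumulate_outcomes(trace, p$usual_care, p$settings)
  expect_equal(out$qalys, 24 * 0.82 / 12) # 1.64 undiscounted QALYs
  expect_equal(out$life_years, 2)
  expect_equal(out$cost_mortality, 0)
  # annualised accrual: one twelfth of the monthly unit cost per cycle
  expect_equal(out$cost_direct, 24 * 2176 / 12)
  expect_equal(out$cost_sick_leave, 24 * 9349 / 12 * 1e-3)
})

test_that("occupancy is conserved and death is absorbing at the base case", {
  p <- default_parameters()
  for (arm in c("usual_care", "pcc")) {
    trace <- run_cohort(p[[arm]], p$settings)
    occ <- as.matrix(trace[, acscea:::acs_states])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
    expect_true(all(occ >= 0))
    expect_true(all(diff(trace$dead) >= 0))
    expect_true(all(trace$new_deaths >= 0))
  }
})

test_that("rewards respond monotonically to risks, utilities, and discounting", {
  p <- default_parameters()
  base <- run_arm(p$pcc, p$settings)

  worse <- param_set(p, "pcc.risks_2y.death_after_remission1", 0.03)
  expect_lt(run_arm(worse$pcc, worse$settings)$qalys, base$qalys)

  nicer <- param_set(p, "pcc.utilities.remission", 0.9)
  expect_gt(run_arm(nicer$pcc, nicer$settings)$qalys, base$qalys)

  at_rate <- function(r) {
    q <- param_set(p, "settings.discount_rate_effects", r)
    q <- param_set(q, "settings.discount_rate_costs", r)
    run_arm(q$pcc, q$settings)
  }
  r0 <- at_rate(0)
  r3 <- at_rate(0.03)
  r5 <- at_rate(0.05)
  for (col in names(r0)) {
    expect_true(r0[[col]] >= r3[[col]] && r3[[col]] >= r5[[col]])
  }
})

test_that("mortality productivity losses value the remaining horizon", {
  # the whole cohort dies during the first cycle: production is lost for
  # months 1..59, valued at the gross wage under per-cycle accrual
  p <- no_discount(zero_risk_params(horizon = 60))
  p <- param_set(p, "settings.cost_accrual", "per_cycle")
  p <- param_set(p, "pcc.risks_2y.death_after_remission1", 1)
  out <- run_arm(p$pcc, p$settings)
  expect_equal(out$cost_mortality, 59 * 46400)
  # and the undiscounted trace accrual agrees with the accumulated total
  trace <- run_cohort(p$pcc, p$settings)
  expect_equal(sum(trace$mortality_productivity_loss), out$cost_mortality)

  # no deaths, no mortality cost
  expect_equal(run_arm(zero_risk_params()$pcc, zero_risk_params()$settings)$cost_mortality, 0)
})

test_that("undiscounted accumulation equals the plain trace sums", {
  p <- no_discount(default_parameters())
  trace <- run_cohort(p$usual_care, p$settings)
  out <- accumulate_outcomes(trace, p$usual_care, p$settings)
  expect_equal(out$qalys, sum(trace$qaly))
  expect_equal(out$life_years, sum(trace$life_years))
  expect_equal(out$cost_direct, sum(trace$direct_cost))
  expect_equal(out$cost_sick_leave, sum(trace$sick_leave_cost))
  expect_equal(out$cost_mortality, sum(trace$mortality_productivity_loss))
  expect_equal(
    out$cost_total,
    out$cost_direct + out$cost_sick_leave + out$cost_mortality
  )

  # mismatched horizon is refused
  p24 <- param_set(p, "settings.horizon_months", 24)
  expect_error(
    accumulate_outcomes(trace, p24$usual_care, p24$settings),
    "horizon"
  )
})

test_that("initial-event month and half-cycle correction behave as flags", {
  p <- default_parameters()
  pi <- param_set(p, "settings.include_initial_event_month", TRUE)
  tr <- run_cohort(pi$pcc, pi$settings)
  expect_equal(tr$initial_event[1], 1)
  expect_equal(tr$remission_1[1], 0)
  # the initial event month is weighted as a relapse month
  expect_equal(tr$qaly[1], 0.67 / 12)

  ph <- param_set(p, "settings.half_cycle_correction", TRUE)
  tr_h <- run_cohort(ph$pcc, ph$settings)
  occ <- as.matrix(tr_h[, acscea:::acs_states])
  expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
  # with mortality, averaging over the cycle accrues fewer life years
  expect_lt(sum(tr_h$life_years), sum(run_cohort(p$pcc, p$settings)$life_years))
})

test_that("cohort engine matches the individual-level microsimulation", {
  p <- param_set(default_parameters(), "settings.horizon_months", 24)
  n <- 50000
  for (arm in c("usual_care", "pcc")) {
    trace <- run_cohort(p[[arm]], p$settings)
    micro <- microsimulate_occupancy(p[[arm]], p$settings, n, seed = 7)
    for (st in acscea:::acs_states) {
      se <- sqrt(pmax(trace[[st]] * (1 - trace[[st]]), 1e-12) / n)
      expect_true(
        all(abs(micro[[st]] - trace[[st]]) < pmax(3.5 * se, 5 / n)),
        label = paste("microsimulation occupancy deviates for", arm, st)
      )
    }
  }
})
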