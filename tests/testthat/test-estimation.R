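test_that("total risk counts qualifying patients per arm", {
  rec <- hand_records()
  r1 <- total_risk(rec, "relapse1")
  expect_equal(r1$total_risk[r1$arm == "usual_care"], 0.5) # 1 of 2
  expect_equal(r1$total_risk[r1$arm == "pcc"], 0.5)
  r2 <- total_risk(rec, "relapse2")
  expect_equal(r2$total_risk[r2$arm == "usual_care"], 0) # nobody relapsed twice
  expect_equal(r2$total_risk[r2$arm == "pcc"], 0.5)
  # events outside the window do not count
  r1w <- total_risk(rec, "relapse1", window_months = 3)
  expect_equal(sum(r1w$events), 0)
  expect_error(total_risk(rec[0, ]), "empty")
})

test_that("monthly risk conversion matches both published conventions", {
  expect_equal(monthly_risk(0.2424, 24), 0.0115, tolerance = 2e-4)
  expect_equal(monthly_risk(0.276, 24, method = "linear"), 0.0115)
  expect_equal(monthly_risk(0, 24), 0)
  expect_equal(monthly_risk(0, 24, "linear"), 0)
  # inverse of the cumulative-risk formula
  expect_equal(1 - (1 - monthly_risk(0.3, 24))^24, 0.3)
  expect_error(monthly_risk(1, 24), "constant-hazard")
})

test_that("cost estimators implement the per-event and per-month averages", {
  rec <- hand_records()
  rel <- relapse_cost(rec)
  expect_equal(rel$cost_per_event[rel$arm == "usual_care"], 40000) # single event
  expect_equal(rel$cost_per_event[rel$arm == "pcc"], 40000) # mean of 50k and 30k
  expect_error(relapse_cost(rec[rec$arm == "usual_care", ][2, ]), "no relapse events")

  rem <- remission_cost(rec)
  # usual care: (23*200 + 24*100) / (23 + 24)
  expect_equal(
    rem$cost_per_month[rem$arm == "usual_care"],
    (23 * 200 + 24 * 100) / 47
  )
  # pcc: patient 3 died at month 12 with 2 relapse months -> 10 remission months
  expect_equal(
    rem$cost_per_month[rem$arm == "pcc"],
    (10 * 300 + 24 * 50) / (10 + 24)
  )
})

test_that("sick-leave costing follows the human-capital rules", {
  s <- default_parameters()$settings
  expect_equal(s$gross_monthly_income / s$working_days_per_month, 2320)

  rec <- hand_records()
  sick <- sick_leave_monthly_cost(rec, s)
  # usual care: one spell of 10 reimbursed days -> (10+14)*2320 over 48 months
  expect_equal(
    sick$cost_per_month[sick$arm == "usual_care"],
    (10 + 14) * 2320 / 48
  )
  # pcc: spells (20, 6) for patient 3 (died month 12), none for patient 4
  expect_equal(
    sick$cost_per_month[sick$arm == "pcc"],
    ((20 + 14) + (6 + 14)) * 2320 / (12 + 24)
  )

  # permanent sick leave accrues a full wage per month from its start
  rec$permanent_sick_leave_start[2] <- 20L
  sick2 <- sick_leave_monthly_cost(rec, s)
  expect_equal(
    sick2$cost_per_month[sick2$arm == "usual_care"],
    ((10 + 14) * 2320 + 4 * 46400) / 48
  )
  # unless it predates the initial event
  rec$pre_existing_permanent_sick_leave[2] <- TRUE
  sick3 <- sick_leave_monthly_cost(rec, s)
  expect_equal(
    sick3$cost_per_month[sick3$arm == "usual_care"],
    (10 + 14) * 2320 / 48
  )
})

test_that("estimators ignore patient ordering and ids", {
  rec <- simulate_patients(150, seed = 8)
  shuffled <- rec[sample.int(nrow(rec)), ]
  shuffled$patient_id <- rev(shuffled$patient_id)
  expect_equal(total_risk(rec, "relapse1"), total_risk(shuffled, "relapse1"))
  expect_equal(relapse_cost(rec), relapse_cost(shuffled))
  expect_equal(remission_cost(rec), remission_cost(shuffled))
  expect_equal(sick_leave_monthly_cost(rec), sick_leave_monthly_cost(shuffled))
})

test_that("fit_parameters recovers ground truth on synthetic cohorts", {
  truth <- default_parameters()
  n <- 4000
  rec <- simulate_patients(n, truth, seed = 21)
  fitted <- fit_parameters(rec)

  for (arm in c("usual_care", "pcc")) {
    # the estimand of the 2-year event proportion is the crude cumulative
    # incidence with death competing from the first remission:
    #   T* = rr1 / (rr1 + rd) * (1 - (1 - rr1 - rd)^24)
    rr1 <- truth[[arm]]$risks_2y$relapse1
    rd <- truth[[arm]]$risks_2y$death_after_remission1
    t_star <- rr1 / (rr1 + rd) * (1 - (1 - rr1 - rd)^24)
    est_m <- monthly_risk(t_star, 24)
    se_tot <- sqrt(t_star * (1 - t_star) / n)
    se_m <- se_tot * (1 - t_star)^(1 / 24 - 1) / 24 # delta method
    expect_lt(abs(fitted[[arm]]$risks_2y$relapse1 - est_m), 3.5 * se_m)

    # cost estimates within 10% at this n (log-normal, CV 0.5)
    expect_equal(
      fitted[[arm]]$costs$relapse1_cost,
      truth[[arm]]$costs$relapse1_cost,
      tolerance = 0.1
    )
    expect_equal(
      fitted[[arm]]$costs$remission1_cost,
      truth[[arm]]$costs$remission1_cost,
      tolerance = 0.05
    )
    expect_equal(
      fitted[[arm]]$costs$sick_leave_monthly,
      truth[[arm]]$costs$sick_leave_monthly,
      tolerance = 0.05
    )
    # literature-sourced rows pass through untouched
    expect_identical(fitted[[arm]]$risks_5y, truth[[arm]]$risks_5y)
    expect_identical(fitted[[arm]]$utilities, truth[[arm]]$utilities)
    expect_identical(
      fitted[[arm]]$risks_2y$death_after_remission1,
      truth[[arm]]$risks_2y$death_after_remission1
    )
  }
  expect_equal(attr(fitted, "estimation")$risk_method, "constant_hazard")

  # the fitted model produces increments close to the ground-truth increments
  base_inc <- compare_arms(truth)$increments$delta_qalys
  fit_inc <- compare_arms(fitted)$increments$delta_qalys
  expect_lt(abs(fit_inc - base_inc), 2.5)

  expect_error(fit_parameters(rec[rec$arm == "pcc", ]), "both arms")
})
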