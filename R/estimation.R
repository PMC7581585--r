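# Parameter estimation from patient-level register-like records: monthly
# relapse risks from 2-year event proportions, per-event relapse costs,
# per-patient-month remission costs, and sick-leave indirect costs by the
# human-capital method (reimbursed days + 14 per spell, day value = gross
# monthly income / working days per month).

patient_columns <- c(
  "patient_id", "arm", "follow_up_months", "relapse_months",
  "inpatient_event_costs", "non_inpatient_costs", "sick_leave_spells",
  "death_month", "permanent_sick_leave_start", "pre_existing_permanent_sick_leave"
)

check_records <- function(records, require_both_arms = FALSE) {
  missing <- setdiff(patient_columns, names(records))
  if (length(missing) > 0) {
    abort(paste0("patient records missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(records) == 0) abort("patient records are empty")
  if (!all(records$arm %in% c("usual_care", "pcc"))) {
    abort('patient arm must be "usual_care" or "pcc"')
  }
  if (require_both_arms && length(unique(records$arm)) < 2) {
    abort("patient records must cover both arms")
  }
  invisible(records)
}

# Months alive within follow-up: death truncates follow-up.
alive_months <- function(records) {
  ifelse(is.na(records$death_month), records$follow_up_months, records$death_month)
}

#' Total relapse risk over an observation window
#'
#' The proportion of patients in each arm with a qualifying event within the
#' window: at least one relapse for `"relapse1"`, at least a second relapse
#' (conditional ordering by month) for `"relapse2"`.
#'
#' @param records Patient record tibble (see [simulate_patients()] for the
#'   schema).
#' @param event `"relapse1"` or `"relapse2"`.
#' @param window_months Observation window in months (default 24).
#' @return A tibble with one row per arm: `arm`, `n`, `events`, `total_risk`.
#' @examples
#' \donttest{
#' total_risk(trial_cohort(), "relapse1")
#' }
#' @export
total_risk <- function(records, event = c("relapse1", "relapse2"), window_months = 24) {
  event <- match.arg(event)
  check_records(records)
  need <- if (event == "relapse1") 1L else 2L
  records |>
    dplyr::mutate(
      qualifies = purrr::map_lgl(
        .data$relapse_months,
        function(m) sum(m < window_months) >= need
      )
    ) |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n = dplyr::n(),
      events = sum(.data$qualifies),
      total_risk = .data$events / .data$n,
      .groups = "drop"
    )
}

#' Monthly risk from a total risk over a period
#'
#' Converts a total (cumulative) risk over `months` cycles into a monthly
#' per-cycle probability. `"constant_hazard"` (default) solves
#' `1 - (1 - total)^(1/months)`; `"linear"` divides, `total / months`.
#'
#' @param total Total risk over the period, in \[0, 1) for
#'   `"constant_hazard"` (vectorised).
#' @param months Period length in months (default 24).
#' @param method Conversion convention.
#' @return Monthly probability (vectorised).
#' @examples
#' monthly_risk(0.2424, 24) # ~0.0115
#' @export
monthly_risk <- function(total, months = 24, method = c("constant_hazard", "linear")) {
  method <- match.arg(method)
  stopifnot(months >= 1, all(total >= 0), all(total <= 1))
  if (method == "constant_hazard") {
    if (any(total == 1)) {
      abort("total risk of 1 has no finite constant-hazard monthly risk")
    }
    1 - (1 - total)^(1 / months)
  } else {
    total / months
  }
}

#' Mean inpatient cost per relapse event
#'
#' Sum of all individual inpatient ACS event costs divided by the number of
#' events, per arm.
#'
#' @inheritParams total_risk
#' @return A tibble with one row per arm: `arm`, `n_events`, `cost_per_event`.
#' @export
relapse_cost <- function(records) {
  check_records(records)
  out <- records |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n_events = sum(lengths(.data$inpatient_event_costs)),
      cost_per_event = sum(unlist(.data$inpatient_event_costs)) / .data$n_events,
      .groups = "drop"
    )
  if (any(out$n_events == 0)) {
    abort(paste0(
      "no relapse events in arm: ",
      paste(out$arm[out$n_events == 0], collapse = ", ")
    ))
  }
  out
}

#' Mean non-inpatient healthcare cost per remission patient-month
#'
#' Total non-inpatient (outpatient, primary care, pharmaceutical) costs
#' divided by the number of patient-months in remission, per arm. A relapse
#' occupies one month, so remission months are alive months minus relapse
#' months; follow-up is truncated at death.
#'
#' @inheritParams total_risk
#' @return A tibble with one row per arm: `arm`, `remission_months`,
#'   `cost_per_month`.
#' @export
remission_cost <- function(records) {
  check_records(records)
  out <- records |>
    dplyr::mutate(
      alive = alive_months(records),
      rem_months = .data$alive - lengths(.data$relapse_months),
      non_inpatient_total = purrr::map_dbl(.data$non_inpatient_costs, sum)
    ) |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      remission_months = sum(.data$rem_months),
      cost_per_month = sum(.data$non_inpatient_total) / .data$remission_months,
      .groups = "drop"
    )
  if (any(out$remission_months <= 0)) {
    abort("no remission patient-months in at least one arm")
  }
  out
}

#' Monthly sick-leave indirect cost by the human-capital method
#'
#' Each reimbursed sickness spell contributes its reimbursed days plus 14 (the
#' unreimbursed qualifying period), valued at the daily production value
#' `gross_monthly_income / working_days_per_month`. Patients who entered
#' permanent sick leave after the initial event additionally contribute one
#' gross monthly income per month from the start of permanent leave; patients
#' already on permanent sick leave before the initial event are excluded from
#' the numerator. The arm total is divided by alive patient-months.
#'
#' @inheritParams total_risk
#' @param settings Global settings list providing `gross_monthly_income` and
#'   `working_days_per_month` (default those of [default_parameters()]).
#' @return A tibble with one row per arm: `arm`, `patient_months`,
#'   `cost_per_month`.
#' @export
sick_leave_monthly_cost <- function(records, settings = default_parameters()$settings) {
  check_records(records)
  day_value <- settings$gross_monthly_income / settings$working_days_per_month
  records |>
    dplyr::mutate(
      alive = alive_months(records),
      spell_cost = purrr::map_dbl(
        .data$sick_leave_spells,
        function(d) sum((d + 14) * day_value)
      ),
      permanent_months = dplyr::if_else(
        is.na(.data$permanent_sick_leave_start),
        0,
        pmax(0, .data$alive - .data$permanent_sick_leave_start)
      ),
      indirect = dplyr::if_else(
        .data$pre_existing_permanent_sick_leave,
        0,
        .data$spell_cost + .data$permanent_months * settings$gross_monthly_income
      )
    ) |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      patient_months = sum(.data$alive),
      cost_per_month = sum(.data$indirect) / .data$patient_months,
      .groups = "drop"
    )
}

#' Estimate model parameters from patient-level records
#'
#' Derives the register-estimable parameters per arm — first-period monthly
#' relapse risks (from 2-year total risks via [monthly_risk()]), relapse costs
#' per event (applied to both relapse states), remission costs per month
#' (applied to all three remission states), and monthly sick-leave indirect
#' costs — and passes every literature-sourced parameter (mortality risks,
#' second-period risks, quality-of-life weights) through unchanged from
#' `defaults`.
#'
#' @inheritParams total_risk
#' @param defaults Parameter object providing the non-estimated fields and the
#'   wage settings (default [default_parameters()]).
#' @param risk_method Conversion convention for [monthly_risk()].
#' @param risk_window_months Observation window for the relapse risks
#'   (default 24).
#' @return A validated `acs_parameters` object with attribute
#'   `estimation` recording the method and window.
#' @export
fit_parameters <- function(records, defaults = default_parameters(),
                           risk_method = c("constant_hazard", "linear"),
                           risk_window_months = 24) {
  risk_method <- match.arg(risk_method)
  check_records(records, require_both_arms = TRUE)
  params <- defaults

  r1 <- total_risk(records, "relapse1", risk_window_months)
  r2 <- total_risk(records, "relapse2", risk_window_months)
  rel <- relapse_cost(records)
  rem <- remission_cost(records)
  sick <- sick_leave_monthly_cost(records, defaults$settings)

  for (arm in c("usual_care", "pcc")) {
    pick <- function(tbl, col) tbl[[col]][tbl$arm == arm]
    params <- param_set(
      params, paste0(arm, ".risks_2y.relapse1"),
      monthly_risk(pick(r1, "total_risk"), risk_window_months, risk_method)
    )
    params <- param_set(
      params, paste0(arm, ".risks_2y.relapse2"),
      monthly_risk(pick(r2, "total_risk"), risk_window_months, risk_method)
    )
    params <- param_set(params, paste0(arm, ".costs.relapse"), pick(rel, "cost_per_event"))
    params <- param_set(params, paste0(arm, ".costs.remission"), pick(rem, "cost_per_month"))
    params <- param_set(
      params, paste0(arm, ".costs.sick_leave_monthly"),
      pick(sick, "cost_per_month")
    )
  }
  attr(params, "estimation") <- list(
    risk_method = risk_method,
    risk_window_months = risk_window_months,
    n = nrow(records)
  )
  params
}
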