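# Monthly-cycle Markov cohort engine. The three clinical states (remission,
# relapse, dead) are expanded to a seven-state space that encodes the relapse
# count, so the process is Markov: initial event, remission 1, relapse 1,
# remission 2, relapse 2, remission 3, dead. A relapse lasts exactly one
# cycle; from relapse the cohort moves to the next remission or dies. Once in
# the third remission, patients remain there or die.

acs_states <- c(
  "initial_event", "remission_1", "relapse_1",
  "remission_2", "relapse_2", "remission_3", "dead"
)

#' Monthly transition matrix for one treatment arm
#'
#' Builds the row-stochastic transition matrix over the seven model states for
#' a given cycle. Cycles are 0-based; cycles before `settings$switch_month`
#' (default 24) use the arm's first-period (`risks_2y`) monthly risks, later
#' cycles the treatment-independent second-period (`risks_5y`) risks. The
#' initial-event state behaves as a relapse-type month feeding the first
#' remission. Relapse states have no self-loop: the cohort exits to death or
#' the next remission after one cycle.
#'
#' @param arm One arm component of an [`acs_parameters`][default_parameters]
#'   object (e.g. `params$pcc`).
#' @param settings The `settings` component of the parameter object.
#' @param month 0-based cycle index.
#' @return A 7 x 7 row-stochastic matrix with dimnames `acs_states`.
#' @examples
#' p <- default_parameters()
#' transition_matrix(p$usual_care, p$settings, month = 3)["relapse_1", ]
#' @export
transition_matrix <- function(arm, settings, month) {
  stopifnot(length(month) == 1, month >= 0)
  r <- if (month < settings$switch_month) arm$risks_2y else arm$risks_5y

  for (i in 1:2) {
    exit <- r[[paste0("relapse", i)]] + r[[paste0("death_after_remission", i)]]
    if (exit > 1) {
      abort(paste0(
        "relapse + death probability from remission ", i,
        " exceeds 1 (", format(exit), ")"
      ))
    }
  }

  P <- matrix(0, 7, 7, dimnames = list(acs_states, acs_states))
  P["initial_event", "dead"] <- r$death_after_relapse1
  P["initial_event", "remission_1"] <- 1 - r$death_after_relapse1
  P["remission_1", "relapse_1"] <- r$relapse1
  P["remission_1", "dead"] <- r$death_after_remission1
  P["remission_1", "remission_1"] <- 1 - r$relapse1 - r$death_after_remission1
  P["relapse_1", "dead"] <- r$death_after_relapse1
  P["relapse_1", "remission_2"] <- 1 - r$death_after_relapse1
  P["remission_2", "relapse_2"] <- r$relapse2
  P["remission_2", "dead"] <- r$death_after_remission2
  P["remission_2", "remission_2"] <- 1 - r$relapse2 - r$death_after_remission2
  P["relapse_2", "dead"] <- r$death_after_relapse2
  P["relapse_2", "remission_3"] <- 1 - r$death_after_relapse2
  P["remission_3", "dead"] <- r$death_after_remission3
  P["remission_3", "remission_3"] <- 1 - r$death_after_remission3
  P["dead", "dead"] <- 1
  P
}

#' Discount factor for a monthly cycle
#'
#' `(1 + annual_rate)^(-month / 12)`; cycle 0 is undiscounted.
#'
#' @param month 0-based cycle index (vectorised).
#' @param annual_rate Annual discount rate as a fraction (>= 0).
#' @return Discount factor(s) in (0, 1].
#' @export
discount_factor <- function(month, annual_rate) {
  stopifnot(annual_rate >= 0)
  (1 + annual_rate)^(-month / 12)
}

# Per-state annual utility weights and monthly cost rates for an arm.
state_utilities <- function(arm) {
  u <- arm$utilities
  c(u$relapse, u$remission, u$relapse, u$remission, u$relapse, u$remission, 0)
}

state_costs <- function(arm) {
  cs <- arm$costs
  c(
    cs$relapse1_cost, cs$remission1_cost, cs$relapse1_cost,
    cs$remission2_cost, cs$relapse2_cost, cs$remission3_cost, 0
  )
}

# Cycle-length factor applied to cost streams. Under the default "annualised"
# convention every reward stream (costs as well as utilities) accrues
# one-twelfth of its unit value per monthly cycle, which is the accounting
# under which the published base case is recovered; "per_cycle" accrues the
# full unit value each month.
cost_cycle_factor <- function(settings) {
  if (identical(settings$cost_accrual, "per_cycle")) 1 else 1 / 12
}

#' Run the cohort model for one treatment arm
#'
#' Propagates the state-occupancy distribution through
#' `settings$horizon_months` monthly cycles and records per-cycle undiscounted
#' reward accruals. The cohort starts with occupancy 1 in the first remission
#' (or in the initial-event state if `settings$include_initial_event_month` is
#' `TRUE`; the initial event is costed and weighted as a relapse month).
#' Rewards accrue on start-of-cycle occupancy, or on the average of the
#' start- and end-of-cycle occupancy when `settings$half_cycle_correction` is
#' `TRUE`.
#'
#' Per cycle the trace records quality-adjusted life years (occupancy times
#' annual utility / 12), life years (alive occupancy / 12), direct healthcare
#' costs (occupancy times state cost rate, including any delivery cost),
#' sick-leave indirect costs (alive occupancy times the arm's monthly
#' sick-leave cost times `settings$sick_leave_scale`), the fraction of the
#' cohort dying during the cycle, and the undiscounted productivity loss those
#' deaths imply over the remaining horizon. All accruals are undiscounted;
#' [accumulate_outcomes()] applies discounting.
#'
#' @inheritParams transition_matrix
#' @return A tibble of class `acs_trace` with one row per cycle: `month`, one
#'   occupancy column per state, `alive`, and the accrual columns `qaly`,
#'   `life_years`, `direct_cost`, `sick_leave_cost`,
#'   `mortality_productivity_loss`, `new_deaths`.
#' @examples
#' p <- default_parameters()
#' trace <- run_cohort(p$usual_care, p$settings)
#' tail(trace$dead, 1) # cumulative mortality at the end of the horizon
#' @export
run_cohort <- function(arm, settings) {
  horizon <- settings$horizon_months
  if (horizon < 1) abort("settings.horizon_months must be at least 1")
  cf <- cost_cycle_factor(settings)
  u <- state_utilities(arm)
  cs <- state_costs(arm)
  wage <- settings$gross_monthly_income

  occ <- setNames(numeric(7), acs_states)
  occ[if (isTRUE(settings$include_initial_event_month)) "initial_event" else "remission_1"] <- 1

  occupancy <- matrix(0, horizon, 7, dimnames = list(NULL, acs_states))
  acc <- matrix(0, horizon, 6, dimnames = list(NULL, c(
    "qaly", "life_years", "direct_cost", "sick_leave_cost",
    "mortality_productivity_loss", "new_deaths"
  )))

  # the process is piecewise time-homogeneous: one matrix per risk period
  P2 <- transition_matrix(arm, settings, 0)
  P5 <- if (horizon > settings$switch_month) {
    transition_matrix(arm, settings, settings$switch_month)
  } else {
    NULL
  }
  for (m in seq_len(horizon) - 1L) {
    P <- if (m < settings$switch_month) P2 else P5
    occ_next <- drop(occ %*% P)
    o <- if (isTRUE(settings$half_cycle_correction)) (occ + occ_next) / 2 else occ
    alive <- 1 - o[["dead"]]
    i <- m + 1L
    occupancy[i, ] <- occ
    acc[i, "qaly"] <- sum(o * u) / 12
    acc[i, "life_years"] <- alive / 12
    acc[i, "direct_cost"] <- sum(o * cs) * cf +
      alive * arm$delivery_cost_per_month * cf +
      if (m == 0) arm$delivery_cost_fixed else 0
    acc[i, "sick_leave_cost"] <- alive * arm$costs$sick_leave_monthly *
      settings$sick_leave_scale * cf
    nd <- occ_next[["dead"]] - occ[["dead"]]
    acc[i, "new_deaths"] <- nd
    # deaths during cycle m lose production from month m + 1 to the horizon
    acc[i, "mortality_productivity_loss"] <- nd * wage * cf * max(0, horizon - 1 - m)
    occ <- occ_next
  }

  trace <- tibble::as_tibble(cbind(
    data.frame(month = seq_len(horizon) - 1L), occupancy, acc
  ))
  trace$alive <- 1 - trace$dead
  structure(trace, class = c("acs_trace", class(trace)))
}

#' Discounted outcomes for one cohort trace
#'
#' Discounts and sums the per-cycle accruals of a trace produced by
#' [run_cohort()]: effects at `settings$discount_rate_effects`, costs at
#' `settings$discount_rate_costs`. Mortality-related productivity losses are
#' valued by the human-capital method: a death during cycle `m` loses the
#' gross monthly income for every month from `m + 1` to the end of the
#' horizon, each discounted at the cost rate.
#'
#' @param trace An `acs_trace` from [run_cohort()] produced under `settings`.
#' @inheritParams transition_matrix
#' @return A one-row tibble: `qalys`, `life_years`, `cost_direct`,
#'   `cost_sick_leave`, `cost_mortality`, `cost_total` (all discounted, per
#'   patient).
#' @export
accumulate_outcomes <- function(trace, arm, settings) {
  horizon <- settings$horizon_months
  if (nrow(trace) != horizon) {
    abort(paste0(
      "trace has ", nrow(trace), " cycles but settings$horizon_months is ", horizon
    ))
  }
  cf <- cost_cycle_factor(settings)
  m <- trace$month
  dfe <- discount_factor(m, settings$discount_rate_effects)
  dfc <- discount_factor(m, settings$discount_rate_costs)

  # discounted value of one death at cycle m: wage stream over months
  # (m + 1)..(horizon - 1), discounted at the cost rate
  wage_stream <- settings$gross_monthly_income * cf *
    discount_factor(seq_len(horizon) - 1L, settings$discount_rate_costs)
  loss_after <- rev(cumsum(rev(wage_stream))) # loss_after[i] = sum over t >= i - 1
  per_death <- c(loss_after[-1], 0) # months strictly after m
  cost_mortality <- sum(trace$new_deaths * per_death)

  tibble::tibble(
    qalys = sum(dfe * trace$qaly),
    life_years = sum(dfe * trace$life_years),
    cost_direct = sum(dfc * trace$direct_cost),
    cost_sick_leave = sum(dfc * trace$sick_leave_cost),
    cost_mortality = cost_mortality,
    cost_total = cost_direct + cost_sick_leave + cost_mortality
  )
}

#' Run one arm end to end
#'
#' Convenience wrapper: [run_cohort()] followed by [accumulate_outcomes()].
#'
#' @inheritParams transition_matrix
#' @return The one-row outcome tibble of [accumulate_outcomes()].
#' @export
run_arm <- function(arm, settings) {
  accumulate_outcomes(run_cohort(arm, settings), arm, settings)
}

#' Plot the state occupancy of a cohort trace
#'
#' @param object An `acs_trace`.
#' @param ... Unused.
#' @return A ggplot object (stacked occupancy area chart).
#' @method autoplot acs_trace
#' @export
autoplot.acs_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "month", dplyr::all_of(acs_states)),
    -"month",
    names_to = "state", values_to = "occupancy"
  )
  long$state <- factor(long$state, levels = acs_states)
  ggplot2::ggplot(long, ggplot2::aes(.data$month, .data$occupancy, fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "month", y = "state occupancy", fill = NULL)
}
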