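# Incremental cost-effectiveness comparison of the two arms: ICER with
# dominance semantics, net monetary benefit, and the three costing
# perspectives reported in the base case.

acs_perspectives <- c("direct_only", "direct_plus_sick_leave", "societal")

perspective_cost <- function(outcomes, perspective) {
  switch(perspective,
    direct_only = outcomes$cost_direct,
    direct_plus_sick_leave = outcomes$cost_direct + outcomes$cost_sick_leave,
    societal = outcomes$cost_total,
    abort(paste0("unknown perspective: ", perspective))
  )
}

#' Incremental cost-effectiveness ratio with dominance semantics
#'
#' Computes `delta_cost / delta_effect` and classifies the quadrant of the
#' cost-effectiveness plane: `"dominant"` (cheaper and more effective),
#' `"dominated"` (costlier and less effective), `"trade_off_ne"` (costlier,
#' more effective), `"trade_off_sw"` (cheaper, less effective), or
#' `"undefined"` when the effect difference is zero (no division is
#' attempted). Raw ICER comparisons against a threshold are ill-defined
#' outside the north-east quadrant, which is why decision rules in this
#' package go through [nmb()] instead.
#'
#' @param delta_cost Incremental cost (vectorised).
#' @param delta_effect Incremental effect, e.g. QALYs (vectorised).
#' @return A tibble with columns `delta_cost`, `delta_effect`, `icer`
#'   (`NA` when undefined), `quadrant`.
#' @examples
#' icer(-222314, 2.70)
#' @export
icer <- function(delta_cost, delta_effect) {
  quadrant <- dplyr::case_when(
    delta_effect == 0 ~ "undefined",
    delta_effect > 0 & delta_cost < 0 ~ "dominant",
    delta_effect < 0 & delta_cost > 0 ~ "dominated",
    delta_effect > 0 ~ "trade_off_ne",
    TRUE ~ "trade_off_sw"
  )
  tibble::tibble(
    delta_cost = delta_cost,
    delta_effect = delta_effect,
    icer = dplyr::if_else(delta_effect == 0, NA_real_, delta_cost / delta_effect),
    quadrant = quadrant
  )
}

#' Net monetary benefit
#'
#' `wtp * delta_effect - delta_cost`. Positive if and only if the intervention
#' is cost-effective at willingness-to-pay `wtp`, in every quadrant of the
#' cost-effectiveness plane.
#'
#' @param delta_cost Incremental cost (vectorised).
#' @param delta_effect Incremental effect in QALYs (vectorised).
#' @param wtp Willingness-to-pay threshold per QALY (>= 0).
#' @return Net monetary benefit, same units as `delta_cost`.
#' @examples
#' nmb(-222314, 2.70, 500000)
#' @export
nmb <- function(delta_cost, delta_effect, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * delta_effect - delta_cost
}

#' Compare person-centred care with usual care
#'
#' Runs the cohort model for both arms under identical settings and reports
#' incremental effects and costs (person-centred care minus usual care),
#' scaled to `settings$cohort_scale` patients (1000 by default), with the
#' ICER, quadrant classification, and net monetary benefit at
#' `settings$wtp_threshold` for each costing perspective: direct healthcare
#' costs only, direct plus sick-leave indirect costs, and the societal
#' perspective adding mortality-related productivity losses.
#'
#' @param params An [`acs_parameters`][default_parameters] object.
#' @return An object of class `acs_cea` with components `arms` (per-arm
#'   discounted outcomes per patient), `increments` (per-`cohort_scale`
#'   component increments), `perspectives` (tibble: one row per perspective
#'   with `delta_cost`, `delta_qalys`, `delta_life_years`, `icer`, `quadrant`,
#'   `nmb`), and `settings`. Use [tidy()] for the perspective table, and
#'   [glance()] for a one-row societal summary.
#' @examples
#' res <- compare_arms(default_parameters())
#' tidy(res)
#' @export
compare_arms <- function(params) {
  params <- validate_parameters(params)
  s <- params$settings
  uc <- run_arm(params$usual_care, s)
  pcc <- run_arm(params$pcc, s)
  arms <- dplyr::bind_rows(
    dplyr::mutate(uc, arm = "usual_care", .before = 1),
    dplyr::mutate(pcc, arm = "pcc", .before = 1)
  )
  k <- s$cohort_scale
  increments <- tibble::tibble(
    delta_qalys = (pcc$qalys - uc$qalys) * k,
    delta_life_years = (pcc$life_years - uc$life_years) * k,
    delta_cost_direct = (pcc$cost_direct - uc$cost_direct) * k,
    delta_cost_sick_leave = (pcc$cost_sick_leave - uc$cost_sick_leave) * k,
    delta_cost_mortality = (pcc$cost_mortality - uc$cost_mortality) * k,
    delta_cost_total = (pcc$cost_total - uc$cost_total) * k
  )
  dc <- vapply(
    acs_perspectives,
    function(p) (perspective_cost(pcc, p) - perspective_cost(uc, p)) * k,
    numeric(1)
  )
  out <- icer(unname(dc), increments$delta_qalys)
  perspectives <- tibble::tibble(
    perspective = acs_perspectives,
    delta_cost = out$delta_cost,
    delta_qalys = increments$delta_qalys,
    delta_life_years = increments$delta_life_years,
    icer = out$icer,
    quadrant = out$quadrant,
    nmb = nmb(out$delta_cost, increments$delta_qalys, s$wtp_threshold)
  )
  structure(
    list(
      arms = arms, increments = increments,
      perspectives = perspectives, settings = s
    ),
    class = "acs_cea"
  )
}

#' @export
print.acs_cea <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "<acs_cea> horizon %d months, per %s patients, WTP %s SEK/QALY\n",
    s$horizon_months, format(s$cohort_scale, big.mark = ","),
    format(s$wtp_threshold, big.mark = ",")
  ))
  cat(sprintf(
    "  incremental QALYs %.2f, life years %.2f\n",
    x$increments$delta_qalys, x$increments$delta_life_years
  ))
  p <- x$perspectives
  for (i in seq_len(nrow(p))) {
    cat(sprintf(
      "  %-22s delta cost %10.0f  ICER %10.0f  (%s)\n",
      p$perspective[i], p$delta_cost[i], p$icer[i], p$quadrant[i]
    ))
  }
  invisible(x)
}

#' Tidy a cost-effectiveness comparison
#'
#' @param x An `acs_cea` object.
#' @param ... Unused.
#' @return The perspective tibble: one row per costing perspective.
#' @method tidy acs_cea
#' @export
tidy.acs_cea <- function(x, ...) {
  x$perspectives
}

#' One-row summary of a cost-effectiveness comparison
#'
#' @param x An `acs_cea` object.
#' @param ... Unused.
#' @return A one-row tibble with the societal-perspective increments, ICER,
#'   quadrant, net monetary benefit, horizon, and willingness-to-pay.
#' @method glance acs_cea
#' @export
glance.acs_cea <- function(x, ...) {
  soc <- dplyr::filter(x$perspectives, .data$perspective == "societal")
  tibble::tibble(
    horizon_months = x$settings$horizon_months,
    wtp = x$settings$wtp_threshold,
    delta_qalys = soc$delta_qalys,
    delta_life_years = soc$delta_life_years,
    delta_cost_total = soc$delta_cost,
    icer = soc$icer,
    quadrant = soc$quadrant,
    nmb = soc$nmb
  )
}
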