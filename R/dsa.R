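# Deterministic sensitivity analyses: discount-rate scenarios, one-way
# parameter sweeps over the intervention arm, and bisection search for the
# parameter value at which the intervention stops being cost-effective.

#' Discount-rate scenario analysis
#'
#' Re-runs the full comparison under the base-case discount rates and the four
#' scenario combinations of 0\% and 5\% rates for effects and costs (both 0\%,
#' both 5\%, effects 0\% with costs 5\%, effects 5\% with costs 0\%). Each
#' scenario differs from `params` only in the two rates.
#'
#' @param params An [`acs_parameters`][default_parameters] object.
#' @param rates Two rates used in the scenario grid (default `c(0, 0.05)`).
#' @return A tibble with one row per scenario and perspective: `scenario`,
#'   `rate_effects`, `rate_costs`, plus the columns of [tidy.acs_cea()].
#' @export
discount_scenarios <- function(params, rates = c(0, 0.05)) {
  s <- params$settings
  grid <- tibble::tibble(
    scenario = c(
      "base_case",
      sprintf("effects_%g_costs_%g", 100 * rates[1], 100 * rates[1]),
      sprintf("effects_%g_costs_%g", 100 * rates[2], 100 * rates[2]),
      sprintf("effects_%g_costs_%g", 100 * rates[1], 100 * rates[2]),
      sprintf("effects_%g_costs_%g", 100 * rates[2], 100 * rates[1])
    ),
    rate_effects = c(s$discount_rate_effects, rates[1], rates[2], rates[1], rates[2]),
    rate_costs = c(s$discount_rate_costs, rates[1], rates[2], rates[2], rates[1])
  )
  purrr::pmap_dfr(grid, function(scenario, rate_effects, rate_costs) {
    p <- param_set(params, "settings.discount_rate_effects", rate_effects)
    p <- param_set(p, "settings.discount_rate_costs", rate_costs)
    dplyr::mutate(
      tidy(compare_arms(p)),
      scenario = scenario, rate_effects = rate_effects, rate_costs = rate_costs,
      .before = 1
    )
  })
}

#' One-way parameter sweep
#'
#' Evaluates the comparison at each supplied value of one parameter (all other
#' parameters at base case). Sweeps are usually addressed at the
#' person-centred care arm (e.g. `"pcc.risks_2y.relapse1"`); shared settings
#' addresses work too.
#'
#' @param params An [`acs_parameters`][default_parameters] object.
#' @param address Dotted parameter address, see [param_set()].
#' @param values Numeric vector of values to evaluate.
#' @param perspective Costing perspective for the reported `nmb` and `icer`
#'   (default `"societal"`).
#' @return A tibble with one row per value: `address`, `value`,
#'   `delta_qalys`, `delta_life_years`, `delta_cost`, `icer`, `quadrant`,
#'   `nmb`.
#' @export
one_way_sweep <- function(params, address, values,
                          perspective = c("societal", "direct_plus_sick_leave", "direct_only")) {
  perspective <- match.arg(perspective)
  purrr::map_dfr(values, function(v) {
    res <- compare_arms(param_set(params, address, v))
    row <- dplyr::filter(tidy(res), .data$perspective == !!perspective)
    dplyr::mutate(row, address = address, value = v, .before = 1)
  })
}

#' Threshold search for cost-effectiveness
#'
#' Finds, by bisection, the value of one intervention-arm parameter at which
#' the net monetary benefit at willingness-to-pay `wtp` crosses zero, i.e. the
#' value at which person-centred care stops (or starts) being cost-effective.
#' The search is deterministic and requires the per-patient NMB to have
#' opposite signs at the bracket ends.
#'
#' @inheritParams one_way_sweep
#' @param wtp Willingness-to-pay threshold (default
#'   `params$settings$wtp_threshold`).
#' @param bracket Length-2 numeric `c(lo, hi)` bracketing the crossing.
#' @param nmb_tol Convergence tolerance on the per-patient NMB in SEK
#'   (default `1e-6`).
#' @param max_iter Maximum bisection iterations (default 200).
#' @return A one-row tibble of class `acs_threshold`: `address`, `base_value`,
#'   `threshold`, `wtp`, `horizon_months`, `perspective`, `converged`,
#'   `iterations`, `nmb_at_threshold` (per patient).
#' @examples
#' \donttest{
#' threshold_search(default_parameters(), "pcc.risks_2y.relapse1",
#'   bracket = c(0.0093, 0.2)
#' )
#' }
#' @export
threshold_search <- function(params, address, wtp = NULL, bracket,
                             perspective = c("societal", "direct_plus_sick_leave", "direct_only"),
                             nmb_tol = 1e-6, max_iter = 200) {
  perspective <- match.arg(perspective)
  wtp <- wtp %||% params$settings$wtp_threshold
  stopifnot(length(bracket) == 2, is.numeric(bracket))
  base_value <- param_get(params, address)
  scale <- params$settings$cohort_scale

  f <- function(v) {
    row <- dplyr::filter(
      tidy(compare_arms(param_set(params, address, v))),
      .data$perspective == !!perspective
    )
    nmb(row$delta_cost, row$delta_qalys, wtp) / scale # per patient
  }

  lo <- min(bracket)
  hi <- max(bracket)
  flo <- f(lo)
  fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    abort(paste0(
      "no NMB sign change in bracket [", format(lo), ", ", format(hi),
      "] for ", address
    ))
  }
  width_tol <- 1e-10 * max(1, abs(hi))
  converged <- FALSE
  iter <- 0L
  mid <- (lo + hi) / 2
  fm <- NA_real_
  while (iter < max_iter) {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < nmb_tol || (hi - lo) < width_tol) {
      converged <- TRUE
      break
    }
    if (flo * fm <= 0) {
      hi <- mid
      fhi <- fm
    } else {
      lo <- mid
      flo <- fm
    }
  }
  out <- tibble::tibble(
    address = address,
    base_value = base_value,
    threshold = mid,
    wtp = wtp,
    horizon_months = params$settings$horizon_months,
    perspective = perspective,
    converged = converged,
    iterations = iter,
    nmb_at_threshold = fm
  )
  structure(out, class = c("acs_threshold", class(out)))
}
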