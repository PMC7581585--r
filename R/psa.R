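# Probabilistic sensitivity analysis: moment-matched beta and log-normal
# parameter distributions, seeded Monte Carlo over the full comparison,
# cost-effectiveness plane and acceptability curve.

#' Beta distribution parameters from mean and variance
#'
#' Moment matching: `alpha = m (m(1 - m)/v - 1)`,
#' `beta = (1 - m) (m(1 - m)/v - 1)`, which requires `v < m(1 - m)`. The
#' constraint is enforced, not clipped: an infeasible variance is an error.
#'
#' @param mean Distribution mean in (0, 1).
#' @param variance Distribution variance, in (0, `mean * (1 - mean)`).
#' @param what Parameter name used in error messages.
#' @return A list with elements `alpha` and `beta`.
#' @examples
#' beta_from_moments(0.67, (0.2 * 0.67)^2)
#' @export
beta_from_moments <- function(mean, variance, what = "parameter") {
  if (!is.numeric(mean) || mean <= 0 || mean >= 1) {
    abort(paste0("beta moment matching for ", what, ": mean must be in (0, 1), got ", format(mean)))
  }
  if (!is.numeric(variance) || variance <= 0) {
    abort(paste0("beta moment matching for ", what, ": variance must be positive"))
  }
  vmax <- mean * (1 - mean)
  if (variance >= vmax) {
    abort(paste0(
      "beta moment matching for ", what, ": variance ", format(variance),
      " is not below mean*(1-mean) = ", format(vmax)
    ))
  }
  nu <- mean * (1 - mean) / variance - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Log-normal distribution parameters from mean and variance
#'
#' Moment matching on the arithmetic (non-logarithmised) scale:
#' `sigma2 = ln(1 + v/m^2)` and `mu = ln(m) - sigma2/2`, so that
#' `exp(mu + sigma2/2)` equals the given mean.
#'
#' @param mean Arithmetic mean (> 0).
#' @param variance Arithmetic variance (>= 0; 0 gives a degenerate
#'   distribution at `mean`).
#' @param what Parameter name used in error messages.
#' @return A list with elements `mu` and `sigma2`.
#' @examples
#' lognormal_from_moments(45307, (0.2 * 45307)^2)
#' @export
lognormal_from_moments <- function(mean, variance, what = "parameter") {
  if (!is.numeric(mean) || mean <= 0) {
    abort(paste0("log-normal moment matching for ", what, ": mean must be positive"))
  }
  if (!is.numeric(variance) || variance < 0) {
    abort(paste0("log-normal moment matching for ", what, ": variance must be non-negative"))
  }
  sigma2 <- log(1 + variance / mean^2)
  list(mu = log(mean) - sigma2 / 2, sigma2 = sigma2)
}

#' Distribution specifications for the probabilistic sensitivity analysis
#'
#' Builds the table of sampled parameters: risks and quality-of-life weights
#' are beta distributed, costs log-normal, each with its base-case value as
#' the mean. The dispersion rule sets the second moment from the mean:
#' `"sd_fraction_of_mean"` (the default) takes the standard deviation as
#' `fraction` times the mean; `"variance_fraction_of_mean"` takes the variance
#' as `fraction` times the mean (this literal rule is infeasible for a
#' utility weight of 0.82 and raises an error, which is why the SD rule is the
#' default).
#'
#' Parameters shared between the two arms in the base case — mortality risks,
#' second-period (5-year) risks, and utility weights — are marked `shared` and
#' drawn once per replicate, inducing between-arm correlation; arm-specific
#' parameters (first-period relapse risks, all costs) are drawn independently
#' per arm. The gross monthly income and delivery costs stay fixed.
#'
#' @param params An [`acs_parameters`][default_parameters] object.
#' @param rule Dispersion rule, see above.
#' @param fraction Dispersion fraction (default 0.2).
#' @return A tibble with columns `address`, `family` (`"beta"` or
#'   `"lognormal"`), `mean`, `variance`, `shared`. Distribution parameters are
#'   validated eagerly, so infeasible rules fail here.
#' @export
psa_distributions <- function(params,
                              rule = c("sd_fraction_of_mean", "variance_fraction_of_mean"),
                              fraction = 0.2) {
  rule <- match.arg(rule)
  stopifnot(fraction >= 0)
  death_fields <- grep("^death", risk_fields, value = TRUE)

  spec_row <- function(address, family, shared) {
    m <- param_get(params, address)
    v <- if (rule == "sd_fraction_of_mean") (fraction * m)^2 else fraction * m
    tibble::tibble(address = address, family = family, mean = m, variance = v, shared = shared)
  }

  specs <- dplyr::bind_rows(
    # arm-specific first-period relapse risks
    purrr::map_dfr(c("usual_care", "pcc"), function(arm) {
      purrr::map_dfr(
        paste0(arm, ".risks_2y.", c("relapse1", "relapse2")),
        spec_row,
        family = "beta", shared = FALSE
      )
    }),
    # shared first-period mortality risks (addressed via usual_care, applied to both)
    purrr::map_dfr(
      paste0("usual_care.risks_2y.", death_fields),
      spec_row,
      family = "beta", shared = TRUE
    ),
    # shared second-period risks
    purrr::map_dfr(
      paste0("usual_care.risks_5y.", risk_fields),
      spec_row,
      family = "beta", shared = TRUE
    ),
    # arm-specific costs
    purrr::map_dfr(c("usual_care", "pcc"), function(arm) {
      purrr::map_dfr(
        paste0(arm, ".costs.", cost_fields),
        spec_row,
        family = "lognormal", shared = FALSE
      )
    }),
    # shared quality-of-life weights
    purrr::map_dfr(
      paste0("usual_care.utilities.", c("relapse", "remission")),
      spec_row,
      family = "beta", shared = TRUE
    )
  )
  # validate eagerly so an infeasible dispersion rule fails at spec time
  purrr::pwalk(specs, function(address, family, mean, variance, shared) {
    if (variance == 0) {
      return(invisible(NULL))
    }
    if (family == "beta") {
      beta_from_moments(mean, variance, what = address)
    } else {
      lognormal_from_moments(mean, variance, what = address)
    }
    invisible(NULL)
  })
  specs
}

# Apply one drawn value to the parameter object: shared rows are written to
# both arms at the same block.field address.
apply_draw <- function(params, address, shared, value) {
  if (!shared) {
    return(param_set(params, address, value, validate = FALSE))
  }
  rest <- sub("^[^.]+\\.", "", address)
  params <- param_set(params, paste0("usual_care.", rest), value, validate = FALSE)
  param_set(params, paste0("pcc.", rest), value, validate = FALSE)
}

draw_value <- function(family, mean, variance) {
  if (variance == 0) {
    return(mean)
  }
  if (family == "beta") {
    ab <- beta_from_moments(mean, variance)
    rbeta(1, ab$alpha, ab$beta)
  } else {
    p <- lognormal_from_moments(mean, variance)
    rlnorm(1, p$mu, sqrt(p$sigma2))
  }
}

#' Draw one parameter replicate
#'
#' Draws every parameter listed in `specs` from the current RNG stream, in
#' spec order (shared parameters once, applied to both arms), and returns the
#' perturbed parameter object. Callers control reproducibility by seeding.
#'
#' @param params An [`acs_parameters`][default_parameters] object.
#' @param specs Distribution table from [psa_distributions()].
#' @return A (non-revalidated) `acs_parameters` object with drawn values.
#' @export
draw_replicate <- function(params, specs) {
  if (nrow(specs) == 0) {
    return(params)
  }
  for (i in seq_len(nrow(specs))) {
    v <- draw_value(specs$family[i], specs$mean[i], specs$variance[i])
    params <- apply_draw(params, specs$address[i], specs$shared[i], v)
  }
  params
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' Runs `n_draws` seeded replicates: each replicate draws every parameter in
#' `specs` ([draw_replicate()]), re-runs the full two-arm comparison, and
#' stores the incremental cost (per perspective) and incremental QALYs, scaled
#' to `settings$cohort_scale` patients. Draw ordering is replicate-major and
#' spec-ordered within a replicate, so results are bit-reproducible for a
#' given seed.
#'
#' @param params An [`acs_parameters`][default_parameters] object.
#' @param specs Distribution table (default `psa_distributions(params)`).
#' @param n_draws Number of Monte Carlo replicates (default 1000, as in the
#'   published analysis).
#' @param seed Integer RNG seed (default 1234; always recorded in the result).
#' @return An object of class `acs_psa`: list with `draws` (tibble:
#'   `replicate`, `delta_qalys`, `delta_life_years`, and one
#'   `delta_cost_<perspective>` column per perspective), `n_draws`, `seed`,
#'   `wtp`, `settings`. `tidy()` returns the draw table; `glance()`
#'   summarises means and the probability of cost-effectiveness; `autoplot()`
#'   draws the cost-effectiveness plane.
#' @examples
#' \donttest{
#' psa <- run_psa(default_parameters(), n_draws = 100, seed = 1)
#' glance(psa)
#' }
#' @export
run_psa <- function(params, specs = psa_distributions(params), n_draws = 1000, seed = 1234) {
  stopifnot(n_draws >= 1)
  params <- validate_parameters(params)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
    add = TRUE
  )
  set.seed(seed)
  s <- params$settings
  k <- s$cohort_scale
  # lean per-replicate path: the draw table is assembled once at the end
  rows <- matrix(NA_real_, n_draws, 5, dimnames = list(NULL, c(
    "delta_qalys", "delta_life_years",
    "delta_cost_direct_only", "delta_cost_direct_plus_sick_leave", "delta_cost_societal"
  )))
  for (i in seq_len(n_draws)) {
    drawn <- draw_replicate(params, specs)
    uc <- run_arm(drawn$usual_care, s)
    pcc <- run_arm(drawn$pcc, s)
    rows[i, ] <- c(
      (pcc$qalys - uc$qalys) * k,
      (pcc$life_years - uc$life_years) * k,
      vapply(
        acs_perspectives,
        function(p) (perspective_cost(pcc, p) - perspective_cost(uc, p)) * k,
        numeric(1)
      )
    )
  }
  draws <- dplyr::mutate(
    tibble::as_tibble(rows),
    replicate = seq_len(n_draws), .before = 1
  )
  structure(
    list(
      draws = draws, n_draws = n_draws, seed = seed,
      wtp = params$settings$wtp_threshold, settings = params$settings
    ),
    class = "acs_psa"
  )
}

psa_cost_column <- function(perspective) {
  perspective <- match.arg(perspective, acs_perspectives)
  paste0("delta_cost_", perspective)
}

ce_indicator <- function(delta_cost, delta_qalys, wtp, method) {
  if (method == "nmb") {
    nmb(delta_cost, delta_qalys, wtp) > 0
  } else {
    # literal ratio ordering: the share of raw ICERs falling below the
    # threshold. Negative ratios from the dominated (north-west) quadrant are
    # counted too, which is exactly what makes this construction unsafe as a
    # decision rule; it is provided because published acceptability curves
    # for dominance-heavy interventions are often built this way.
    dplyr::if_else(
      delta_qalys == 0,
      delta_cost < 0,
      delta_cost / delta_qalys < wtp
    )
  }
}

#' Probability that the intervention is cost-effective
#'
#' Fraction of PSA replicates classified cost-effective at willingness-to-pay
#' `wtp`. The default method counts replicates with positive net monetary
#' benefit, which is correct in every quadrant of the cost-effectiveness
#' plane. `method = "icer_ordering"` instead counts replicates whose raw
#' ratio `delta_cost / delta_qalys` falls below `wtp` — the construction many
#' published acceptability curves use, which differs whenever draws land in
#' the dominated (less effective, more costly) quadrant, because their
#' negative ratios also fall below the threshold.
#'
#' @param psa An `acs_psa` object from [run_psa()].
#' @param wtp Willingness-to-pay per QALY (default the stored threshold).
#' @param perspective Costing perspective (default `"societal"`).
#' @param method `"nmb"` (default) or `"icer_ordering"`, see above.
#' @return A fraction in \[0, 1\].
#' @export
prob_cost_effective <- function(psa, wtp = psa$wtp, perspective = "societal",
                                method = c("nmb", "icer_ordering")) {
  method <- match.arg(method)
  col <- psa_cost_column(perspective)
  mean(ce_indicator(psa$draws[[col]], psa$draws$delta_qalys, wtp, method))
}

#' Cost-effectiveness acceptability curve
#'
#' Probability of cost-effectiveness (positive net monetary benefit) at each
#' willingness-to-pay value in `wtp_grid`.
#'
#' @inheritParams prob_cost_effective
#' @param wtp_grid Non-empty numeric vector of willingness-to-pay values.
#' @return A tibble of class `acs_ceac` with columns `wtp`, `probability`,
#'   `perspective`, `method`; `autoplot()` draws the curve.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 1e6, by = 20000), perspective = "societal",
                 method = c("nmb", "icer_ordering")) {
  if (length(wtp_grid) == 0) abort("wtp_grid must be non-empty")
  method <- match.arg(method)
  col <- psa_cost_column(perspective)
  out <- tibble::tibble(
    wtp = as.numeric(wtp_grid),
    probability = vapply(
      wtp_grid,
      function(w) mean(ce_indicator(psa$draws[[col]], psa$draws$delta_qalys, w, method)),
      numeric(1)
    ),
    perspective = perspective,
    method = method
  )
  structure(out, class = c("acs_ceac", class(out)))
}

#' @export
print.acs_psa <- function(x, ...) {
  cat(sprintf(
    "<acs_psa> %d draws (seed %s), horizon %d months\n",
    x$n_draws, format(x$seed), x$settings$horizon_months
  ))
  cat(sprintf(
    "  P(cost-effective at WTP %s, societal) = %.3f\n",
    format(x$wtp, big.mark = ","), prob_cost_effective(x)
  ))
  invisible(x)
}

#' @method tidy acs_psa
#' @export
tidy.acs_psa <- function(x, ...) {
  x$draws
}

#' @method glance acs_psa
#' @export
glance.acs_psa <- function(x, ...) {
  tibble::tibble(
    n_draws = x$n_draws,
    seed = x$seed,
    wtp = x$wtp,
    mean_delta_qalys = mean(x$draws$delta_qalys),
    mean_delta_cost_societal = mean(x$draws$delta_cost_societal),
    prob_ce_direct_only = prob_cost_effective(x, perspective = "direct_only"),
    prob_ce_direct_plus_sick_leave = prob_cost_effective(x, perspective = "direct_plus_sick_leave"),
    prob_ce_societal = prob_cost_effective(x, perspective = "societal")
  )
}

#' Cost-effectiveness plane
#'
#' @param object An `acs_psa` object.
#' @param perspective Costing perspective (default `"societal"`).
#' @param ... Unused.
#' @return A ggplot object: incremental (QALY, cost) pairs with the
#'   willingness-to-pay line.
#' @method autoplot acs_psa
#' @export
autoplot.acs_psa <- function(object, perspective = "societal", ...) {
  col <- psa_cost_column(perspective)
  d <- dplyr::rename(object$draws, delta_cost = dplyr::all_of(col))
  ggplot2::ggplot(d, ggplot2::aes(.data$delta_qalys, .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = object$wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(
      x = sprintf("incremental QALYs (per %s patients)", format(object$settings$cohort_scale, big.mark = ",")),
      y = "incremental cost (SEK)",
      title = sprintf("Cost-effectiveness plane (%s)", perspective)
    )
}

#' @method autoplot acs_ceac
#' @export
autoplot.acs_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "willingness-to-pay (SEK per QALY)",
      y = "probability cost-effective",
      title = "Cost-effectiveness acceptability curve"
    )
}
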