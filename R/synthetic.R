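# Synthetic register-like data. Individual monthly state paths are simulated
# from the same transition rules the cohort engine uses, so the generator
# doubles as an independent microsimulation cross-check of the cohort
# recursion; around the paths it emits the register quantities the estimators
# consume (inpatient event costs, non-inpatient monthly costs, reimbursed
# sick-leave spells, deaths).

# Evaluate code with a temporary RNG seed, restoring any prior RNG state.
with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    } else if (exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    },
    add = TRUE
  )
  set.seed(seed)
  force(code)
}

#' Simulate individual monthly state paths
#'
#' Simulates `n` independent patients through the seven-state monthly
#' transition process of one arm, using exactly the matrices that
#' [transition_matrix()] builds. Vectorised over patients.
#'
#' @inheritParams transition_matrix
#' @param n Number of patients.
#' @param seed Optional integer seed (`NULL` uses the current RNG stream).
#' @return An integer matrix of `n` rows and `horizon_months + 1` columns;
#'   entry `[i, m + 1]` is the state index (into `acs_states`) of patient `i`
#'   at the start of month `m`.
#' @export
simulate_state_paths <- function(arm, settings, n, seed = NULL) {
  run <- function() {
    horizon <- settings$horizon_months
    start <- if (isTRUE(settings$include_initial_event_month)) 1L else 2L
    paths <- matrix(0L, n, horizon + 1L)
    state <- rep.int(start, n)
    paths[, 1L] <- state
    cum2 <- t(apply(transition_matrix(arm, settings, 0), 1, cumsum))
    cum5 <- t(apply(transition_matrix(arm, settings, settings$switch_month), 1, cumsum))
    for (m in seq_len(horizon) - 1L) {
      cum <- if (m < settings$switch_month) cum2 else cum5
      u <- pmax(runif(n), .Machine$double.xmin)
      nxt <- state
      for (k in unique(state)) {
        idx <- which(state == k)
        nxt[idx] <- findInterval(u[idx], cum[k, ], left.open = TRUE) + 1L
      }
      state <- nxt
      paths[, m + 2L] <- state
    }
    paths
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Occupancy trace from an individual-level microsimulation
#'
#' State-occupancy fractions of `n` simulated patients at the start of each
#' month, directly comparable with the occupancy columns of [run_cohort()].
#' Used as the package's stochastic cross-check of the deterministic cohort
#' recursion: the maximum absolute deviation shrinks as `n^(-1/2)`.
#'
#' @inheritParams simulate_state_paths
#' @return A tibble with `month` (0-based, `horizon_months` rows) and one
#'   occupancy-fraction column per state, plus attribute `n`.
#' @export
microsimulate_occupancy <- function(arm, settings, n, seed = NULL) {
  paths <- simulate_state_paths(arm, settings, n, seed)
  horizon <- settings$horizon_months
  occ <- vapply(
    seq_len(horizon),
    function(m) tabulate(paths[, m], nbins = 7L) / n,
    numeric(7)
  )
  out <- tibble::as_tibble(t(occ), .name_repair = ~acs_states)
  out <- dplyr::mutate(out, month = seq_len(horizon) - 1L, .before = 1)
  attr(out, "n") <- n
  out
}

relapse_state_idx <- c(3L, 5L)
remission_state_idx <- c(2L, 4L, 6L)
dead_state_idx <- 7L

# log-normal draws with a given arithmetic mean and coefficient of variation
rlnorm_mean_cv <- function(n, mean, cv) {
  if (n == 0) {
    return(numeric(0))
  }
  if (mean == 0 || cv == 0) {
    return(rep.int(mean, n))
  }
  p <- lognormal_from_moments(mean, (cv * mean)^2)
  rlnorm(n, p$mu, sqrt(p$sigma2))
}

# Spell rate (spells per patient-year) at which the expected human-capital
# cost per patient-month equals the arm's ground-truth sick-leave row.
calibrated_spell_rate <- function(sick_monthly, settings, mean_reimbursed_days) {
  day_value <- settings$gross_monthly_income / settings$working_days_per_month
  sick_monthly * 12 / ((mean_reimbursed_days + 14) * day_value)
}

#' Generate a synthetic register-like patient cohort
#'
#' Simulates patient-level records with the statistical structure the
#' estimators assume: monthly state paths from the ground-truth parameters
#' (relapse months, deaths), log-normal inpatient costs around the arm's
#' relapse cost for each relapse month, log-normal non-inpatient monthly costs
#' around the remission cost for each remission month, and Poisson
#' sick-leave spells with geometric reimbursed-day counts. By default the
#' spell rate is calibrated per arm so that the expected human-capital cost
#' per patient-month equals the arm's ground-truth monthly sick-leave cost,
#' making the generator-estimator pair self-consistent.
#'
#' @param n_per_arm Patients per arm: a single count applied to both arms, or
#'   a named vector like `c(usual_care = 59, pcc = 58)`.
#' @param params Ground-truth [`acs_parameters`][default_parameters]; the
#'   follow-up length is `params$settings$horizon_months`.
#' @param event_cost_cv Coefficient of variation of inpatient event costs
#'   (default 0.5).
#' @param monthly_cost_cv Coefficient of variation of non-inpatient monthly
#'   costs (default 0.5).
#' @param sick_leave_spell_rate Reimbursed spells per patient-year; `NULL`
#'   (default) calibrates it per arm from the ground-truth sick-leave cost.
#' @param mean_reimbursed_days Mean reimbursed days per spell (default 30,
#'   geometric, minimum 1).
#' @param seed Integer seed; the cohort is bit-identical for a given seed.
#' @return A patient-record tibble with columns `patient_id`, `arm`,
#'   `follow_up_months`, `relapse_months` (list of 0-based month indices),
#'   `inpatient_event_costs` (list, SEK per event), `non_inpatient_costs`
#'   (list, SEK per remission month), `sick_leave_spells` (list of reimbursed
#'   day counts), `death_month` (`NA` if alive at the end of follow-up),
#'   `permanent_sick_leave_start`, `pre_existing_permanent_sick_leave`.
#' @examples
#' \donttest{
#' records <- simulate_patients(100, seed = 1)
#' total_risk(records, "relapse1")
#' }
#' @export
simulate_patients <- function(n_per_arm, params = default_parameters(),
                              event_cost_cv = 0.5, monthly_cost_cv = 0.5,
                              sick_leave_spell_rate = NULL,
                              mean_reimbursed_days = 30, seed = 1) {
  params <- validate_parameters(params)
  stopifnot(mean_reimbursed_days >= 1, event_cost_cv >= 0, monthly_cost_cv >= 0)
  if (length(n_per_arm) == 1 && is.null(names(n_per_arm))) {
    n_per_arm <- c(usual_care = n_per_arm, pcc = n_per_arm)
  }
  stopifnot(all(c("usual_care", "pcc") %in% names(n_per_arm)), all(n_per_arm >= 1))
  s <- params$settings
  horizon <- s$horizon_months

  with_seed(seed, {
    per_arm <- purrr::imap(n_per_arm[c("usual_care", "pcc")], function(n, arm_name) {
      arm <- params[[arm_name]]
      n <- as.integer(n)
      paths <- simulate_state_paths(arm, s, n)[, seq_len(horizon), drop = FALSE]
      state_costs_inpatient <- c(arm$costs$relapse1_cost, arm$costs$relapse2_cost)
      state_costs_remission <- c(
        arm$costs$remission1_cost, arm$costs$remission2_cost, arm$costs$remission3_cost
      )
      spell_rate <- sick_leave_spell_rate %||%
        calibrated_spell_rate(arm$costs$sick_leave_monthly, s, mean_reimbursed_days)

      death_month <- rep(NA_integer_, n)
      relapse_months <- vector("list", n)
      inpatient_event_costs <- vector("list", n)
      non_inpatient_costs <- vector("list", n)
      sick_leave_spells <- vector("list", n)
      alive <- integer(n)
      for (i in seq_len(n)) {
        path <- paths[i, ]
        dead_at <- which(path == dead_state_idx)
        if (length(dead_at) > 0) death_month[i] <- dead_at[1] - 1L
        rel <- which(path %in% relapse_state_idx) - 1L
        rem <- which(path %in% remission_state_idx) - 1L
        relapse_months[[i]] <- as.integer(rel)
        inpatient_event_costs[[i]] <- rlnorm_mean_cv(length(rel), 1, event_cost_cv) *
          state_costs_inpatient[match(path[rel + 1L], relapse_state_idx)]
        non_inpatient_costs[[i]] <- rlnorm_mean_cv(length(rem), 1, monthly_cost_cv) *
          state_costs_remission[match(path[rem + 1L], remission_state_idx)]
        alive[i] <- if (is.na(death_month[i])) horizon else death_month[i]
        n_spells <- rpois(1, spell_rate * alive[i] / 12)
        sick_leave_spells[[i]] <- 1L + rgeom(n_spells, prob = 1 / mean_reimbursed_days)
      }
      tibble::tibble(
        patient_id = sprintf("%s_%05d", substr(arm_name, 1, 2), seq_len(n)),
        arm = arm_name,
        follow_up_months = horizon,
        relapse_months = relapse_months,
        inpatient_event_costs = inpatient_event_costs,
        non_inpatient_costs = non_inpatient_costs,
        sick_leave_spells = sick_leave_spells,
        death_month = death_month,
        permanent_sick_leave_start = NA_integer_,
        pre_existing_permanent_sick_leave = FALSE
      )
    })
    dplyr::bind_rows(per_arm)
  })
}

#' Small fixed trial-sized cohort
#'
#' A synthetic stand-in for the trial population (117 patients under 65,
#' split 59 usual care / 58 person-centred care, followed for 24 months),
#' generated from the reference parameters. Used for smoke tests of the
#' estimation pipeline and the command-line interface.
#'
#' @param seed Integer seed (default 1).
#' @return A 117-row patient-record tibble, see [simulate_patients()].
#' @export
trial_cohort <- function(seed = 1) {
  params <- param_set(default_parameters(), "settings.horizon_months", 24)
  simulate_patients(c(usual_care = 59, pcc = 58), params, seed = seed)
}
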