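# Model parameterisation: reference values, config I/O, validation, and
# dotted-address access used by the sensitivity analyses.

risk_fields <- c(
  "relapse1", "relapse2",
  "death_after_relapse1", "death_after_relapse2",
  "death_after_remission1", "death_after_remission2", "death_after_remission3"
)

cost_fields <- c(
  "relapse1_cost", "relapse2_cost",
  "remission1_cost", "remission2_cost", "remission3_cost",
  "sick_leave_monthly"
)

#' Reference model parameters
#'
#' Returns the full base-case parameter set for the two treatment arms (usual
#' care and person-centred care), as published for the Swedish trial cohort of
#' ACS patients under 65: monthly transition risks for the first two years
#' (arm-specific relapse risks, shared mortality risks), treatment-independent
#' risks for years 2-5, state-related monthly healthcare costs, monthly
#' sick-leave indirect costs, quality-of-life weights, and global settings
#' (3\% annual discounting of costs and effects, average gross monthly income
#' of SEK 46,400, willingness-to-pay threshold of SEK 500,000 per QALY,
#' 60-month horizon with the risk regime switching at month 24, results
#' reported per 1000 patients).
#'
#' All probabilities are monthly per-cycle probabilities. Both arms share the
#' quality-of-life weights and mortality risks in this default set, but the
#' returned structure permits them to differ.
#'
#' @return An object of class `acs_parameters`: a nested list with elements
#'   `usual_care`, `pcc` (each with `risks_2y`, `risks_5y`, `costs`,
#'   `utilities`, `delivery_cost_fixed`, `delivery_cost_per_month`) and
#'   `settings`.
#' @seealso [read_parameters()], [param_set()], [compare_arms()]
#' @examples
#' p <- default_parameters()
#' p$pcc$risks_2y$relapse1
#' tidy(p)
#' @export
default_parameters <- function() {
  shared_deaths_2y <- list(
    death_after_relapse1 = 0.0248,
    death_after_relapse2 = 0.0248,
    death_after_remission1 = 0.0106,
    death_after_remission2 = 0.0115,
    death_after_remission3 = 0.0115
  )
  risks_5y <- list(
    relapse1 = 0.0062,
    relapse2 = 0.0062,
    death_after_relapse1 = 0.0037,
    death_after_relapse2 = 0.0037,
    death_after_remission1 = 0.0022,
    death_after_remission2 = 0.0022,
    death_after_remission3 = 0.0022
  )
  utilities <- list(relapse = 0.67, remission = 0.82)

  arm <- function(relapse1, relapse2, relapse_cost, remission_cost, sick) {
    list(
      risks_2y = c(list(relapse1 = relapse1, relapse2 = relapse2), shared_deaths_2y),
      risks_5y = risks_5y,
      costs = list(
        relapse1_cost = relapse_cost,
        relapse2_cost = relapse_cost,
        remission1_cost = remission_cost,
        remission2_cost = remission_cost,
        remission3_cost = remission_cost,
        sick_leave_monthly = sick
      ),
      utilities = utilities,
      delivery_cost_fixed = 0,
      delivery_cost_per_month = 0
    )
  }

  params <- list(
    usual_care = arm(0.0115, 0.0035, 45307, 2176, 9349),
    pcc = arm(0.0093, 0.0056, 39824, 2223, 8250),
    settings = list(
      discount_rate_costs = 0.03,
      discount_rate_effects = 0.03,
      gross_monthly_income = 46400,
      working_days_per_month = 20,
      wtp_threshold = 500000,
      horizon_months = 60,
      switch_month = 24,
      cohort_scale = 1000,
      include_initial_event_month = FALSE,
      half_cycle_correction = FALSE,
      cost_accrual = "annualised",
      sick_leave_scale = 1e-3
    )
  )
  structure(params, class = "acs_parameters")
}

#' Read model parameters from a YAML configuration file
#'
#' Any field absent from the file inherits the corresponding value from
#' [default_parameters()]. The file mirrors the nested structure of the
#' parameter object; in addition, top-level keys containing a dot are treated
#' as dotted override addresses (e.g. `pcc.risks_2y.relapse1: 0.01`), applied
#' after the nested merge. The merged object is validated before it is
#' returned.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) configuration file.
#' @return A validated `acs_parameters` object.
#' @seealso [write_parameters()], [param_set()]
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("parameter file not found: ", path))
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) {
    abort(paste0("malformed parameter file (expected a mapping): ", path))
  }
  dotted <- names(cfg)[grepl(".", names(cfg), fixed = TRUE)]
  nested <- cfg[setdiff(names(cfg), dotted)]
  params <- unclass(default_parameters())
  params <- modifyList(params, nested)
  params <- structure(params, class = "acs_parameters")
  for (addr in dotted) {
    params <- param_set(params, addr, cfg[[addr]], validate = FALSE)
  }
  validate_parameters(params)
}

#' Write model parameters to a YAML file
#'
#' The written file reproduces every field, so
#' `read_parameters(write_parameters(p, f))` round-trips exactly.
#'
#' @param params An `acs_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  params <- validate_parameters(params)
  yaml::write_yaml(unclass(params), path, precision = 17)
  invisible(path)
}

#' Validate a model parameter object
#'
#' Checks every invariant of the parameter set: probabilities and utilities in
#' \[0, 1\], the total monthly exit probability from each remission state
#' (relapse plus death) at most 1, non-negative costs and discount rates, and
#' consistent global settings. Errors name the offending field.
#'
#' @param params An `acs_parameters` object (or a bare list with the same
#'   structure).
#' @return The validated object, classed `acs_parameters`, invisibly usable in
#'   a pipe.
#' @export
validate_parameters <- function(params) {
  p <- unclass(params)
  for (nm in c("usual_care", "pcc", "settings")) {
    if (is.null(p[[nm]])) abort(paste0("parameters missing component: ", nm))
  }
  bad <- function(field, msg) abort(paste0("invalid parameter `", field, "`: ", msg))

  for (arm in c("usual_care", "pcc")) {
    a <- p[[arm]]
    for (block in c("risks_2y", "risks_5y")) {
      r <- a[[block]]
      for (f in risk_fields) {
        v <- r[[f]]
        addr <- paste(arm, block, f, sep = ".")
        if (is.null(v) || !is.numeric(v) || length(v) != 1 || is.na(v)) {
          bad(addr, "must be a single number")
        }
        if (v < 0 || v > 1) bad(addr, "probability outside [0, 1]")
      }
      for (i in 1:3) {
        rel <- if (i < 3) r[[paste0("relapse", i)]] else 0
        dth <- r[[paste0("death_after_remission", i)]]
        if (rel + dth > 1) {
          bad(
            paste(arm, block, paste0("remission", i), sep = "."),
            "relapse + death probability exceeds 1"
          )
        }
      }
    }
    for (f in cost_fields) {
      v <- a$costs[[f]]
      addr <- paste(arm, "costs", f, sep = ".")
      if (is.null(v) || !is.numeric(v) || length(v) != 1 || is.na(v)) {
        bad(addr, "must be a single number")
      }
      if (v < 0) bad(addr, "cost must be non-negative")
    }
    for (f in c("relapse", "remission")) {
      v <- a$utilities[[f]]
      addr <- paste(arm, "utilities", f, sep = ".")
      if (is.null(v) || v < 0 || v > 1) bad(addr, "QALY weight outside [0, 1]")
    }
    for (f in c("delivery_cost_fixed", "delivery_cost_per_month")) {
      if (a[[f]] < 0) bad(paste(arm, f, sep = "."), "delivery cost must be non-negative")
    }
  }

  s <- p$settings
  for (f in c("discount_rate_costs", "discount_rate_effects")) {
    if (s[[f]] < 0) bad(paste0("settings.", f), "discount rate must be non-negative")
  }
  if (s$horizon_months < 1) bad("settings.horizon_months", "must be at least 1")
  if (s$gross_monthly_income < 0) bad("settings.gross_monthly_income", "must be non-negative")
  if (s$working_days_per_month <= 0) bad("settings.working_days_per_month", "must be positive")
  if (s$wtp_threshold < 0) bad("settings.wtp_threshold", "must be non-negative")
  if (s$cohort_scale <= 0) bad("settings.cohort_scale", "must be positive")
  if (s$sick_leave_scale < 0) bad("settings.sick_leave_scale", "must be non-negative")
  if (!s$cost_accrual %in% c("annualised", "per_cycle")) {
    bad("settings.cost_accrual", 'must be "annualised" or "per_cycle"')
  }
  structure(p, class = "acs_parameters")
}

# Resolve a dotted address to its list path(s). Aliases expand to several
# concrete fields so a single sweep can move a whole cost block:
#   <arm>.costs.relapse   -> relapse1_cost, relapse2_cost
#   <arm>.costs.remission -> remission1_cost, remission2_cost, remission3_cost
resolve_address <- function(address) {
  parts <- strsplit(address, ".", fixed = TRUE)[[1]]
  if (length(parts) == 3 && parts[2] == "costs" && parts[3] == "relapse") {
    return(lapply(c("relapse1_cost", "relapse2_cost"), function(f) c(parts[1:2], f)))
  }
  if (length(parts) == 3 && parts[2] == "costs" && parts[3] == "remission") {
    return(lapply(
      c("remission1_cost", "remission2_cost", "remission3_cost"),
      function(f) c(parts[1:2], f)
    ))
  }
  list(parts)
}

#' Get or set a parameter by dotted address
#'
#' Addresses mirror the nested structure, e.g. `"pcc.risks_2y.relapse1"` or
#' `"settings.discount_rate_costs"`. Two aliases address whole cost blocks in
#' one step: `"<arm>.costs.relapse"` (both relapse-state costs) and
#' `"<arm>.costs.remission"` (all three remission-state costs); `param_get`
#' returns the first field of an alias (the fields are equal in the default
#' set).
#'
#' @param params An `acs_parameters` object.
#' @param address Dotted path into the parameter structure.
#' @param value Replacement value (scalar numeric or logical).
#' @param validate Re-validate after setting (default `TRUE`).
#' @return `param_get`: the addressed value. `param_set`: the modified
#'   `acs_parameters` object.
#' @examples
#' p <- default_parameters()
#' param_get(p, "usual_care.costs.relapse1_cost")
#' p2 <- param_set(p, "pcc.risks_2y.relapse1", 0.011)
#' @export
param_get <- function(params, address) {
  path <- resolve_address(address)[[1]]
  v <- tryCatch(
    Reduce(function(x, i) x[[i]], path, unclass(params)),
    error = function(e) NULL
  )
  if (is.null(v)) abort(paste0("unresolvable parameter address: ", address))
  v
}

#' @rdname param_get
#' @export
param_set <- function(params, address, value, validate = TRUE) {
  p <- unclass(params)
  for (path in resolve_address(address)) {
    existing <- tryCatch(
      Reduce(function(x, i) x[[i]], path, p),
      error = function(e) NULL
    )
    if (is.null(existing)) abort(paste0("unresolvable parameter address: ", address))
    p <- purrr::assign_in(p, as.list(path), value)
  }
  p <- structure(p, class = "acs_parameters")
  if (validate) p <- validate_parameters(p)
  p
}

#' @export
print.acs_parameters <- function(x, ...) {
  s <- x$settings
  cat("<acs_parameters>\n")
  cat(sprintf(
    "  horizon %d months (risk switch at month %d), discount %g%%/%g%% (costs/effects)\n",
    s$horizon_months, s$switch_month,
    100 * s$discount_rate_costs, 100 * s$discount_rate_effects
  ))
  cat(sprintf(
    "  WTP %s SEK/QALY, results per %s patients\n",
    format(s$wtp_threshold, big.mark = ","), format(s$cohort_scale, big.mark = ",")
  ))
  cat(sprintf(
    "  2y relapse-1 risk: usual care %.4f, PCC %.4f\n",
    x$usual_care$risks_2y$relapse1, x$pcc$risks_2y$relapse1
  ))
  invisible(x)
}

#' Tidy a parameter object into a long tibble
#'
#' @param x An `acs_parameters` object.
#' @param ... Unused.
#' @return A tibble with columns `component` (arm or `"settings"`), `block`,
#'   `parameter`, `value`.
#' @method tidy acs_parameters
#' @export
tidy.acs_parameters <- function(x, ...) {
  p <- unclass(x)
  rows <- list()
  for (arm in c("usual_care", "pcc")) {
    a <- p[[arm]]
    for (blk in c("risks_2y", "risks_5y", "costs", "utilities")) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        component = arm, block = blk,
        parameter = names(a[[blk]]),
        value = unlist(a[[blk]], use.names = FALSE)
      )
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      component = arm, block = "delivery",
      parameter = c("delivery_cost_fixed", "delivery_cost_per_month"),
      value = c(a$delivery_cost_fixed, a$delivery_cost_per_month)
    )
  }
  sset <- p$settings[vapply(p$settings, is.numeric, logical(1))]
  rows[[length(rows) + 1]] <- tibble::tibble(
    component = "settings", block = "settings",
    parameter = names(sset), value = unlist(sset, use.names = FALSE)
  )
  dplyr::bind_rows(rows)
}
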