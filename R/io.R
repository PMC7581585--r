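# Flat-file serialisation of patient records: one row per patient,
# list-valued fields as semicolon-separated values, UTF-8 CSV with a header
# and dot decimal separator.

join_field <- function(x, digits = 6) {
  vapply(
    x,
    function(v) paste(format(v, digits = digits, scientific = FALSE, trim = TRUE), collapse = ";"),
    character(1)
  )
}

split_field <- function(x, as_integer = FALSE) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) {
      if (as_integer) integer(0) else numeric(0)
    } else {
      parts <- as.numeric(strsplit(v, ";", fixed = TRUE)[[1]])
      if (as_integer) as.integer(parts) else parts
    }
  })
}

#' Read and write patient records as CSV
#'
#' One row per patient; the list-valued fields (`relapse_months`,
#' `inpatient_event_costs`, `non_inpatient_costs`, `sick_leave_spells`) are
#' stored as semicolon-separated values within a cell. Writing then reading
#' reproduces the records.
#'
#' @param records A patient-record tibble (see [simulate_patients()]).
#' @param path CSV file path.
#' @return `write_patients`: `path` invisibly. `read_patients`: the
#'   patient-record tibble.
#' @export
write_patients <- function(records, path) {
  check_records(records)
  flat <- dplyr::mutate(
    records,
    relapse_months = join_field(.data$relapse_months),
    inpatient_event_costs = join_field(.data$inpatient_event_costs, digits = 10),
    non_inpatient_costs = join_field(.data$non_inpatient_costs, digits = 10),
    sick_leave_spells = join_field(.data$sick_leave_spells)
  )
  readr::write_csv(flat, path)
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  flat <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      arm = readr::col_character(),
      follow_up_months = readr::col_integer(),
      relapse_months = readr::col_character(),
      inpatient_event_costs = readr::col_character(),
      non_inpatient_costs = readr::col_character(),
      sick_leave_spells = readr::col_character(),
      death_month = readr::col_integer(),
      permanent_sick_leave_start = readr::col_integer(),
      pre_existing_permanent_sick_leave = readr::col_logical()
    )
  )
  records <- dplyr::mutate(
    flat,
    relapse_months = split_field(.data$relapse_months, as_integer = TRUE),
    inpatient_event_costs = split_field(.data$inpatient_event_costs),
    non_inpatient_costs = split_field(.data$non_inpatient_costs),
    sick_leave_spells = split_field(.data$sick_leave_spells, as_integer = TRUE)
  )
  check_records(records)
  records
}
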