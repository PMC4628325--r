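#' Read a longitudinal cohort table from CSV
#'
#' Expects a UTF-8, '.'-decimal CSV with header columns `patient_id`,
#' `lesion_id`, `timepoint_index`, `reader_id`, `volume_cm3`, the schema
#' written by [write_cohort_csv()]. The table is validated (positive
#' volumes, unique keys, baseline present in every series).
#'
#' @param path Path to the CSV file.
#' @return A validated cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      lesion_id = readr::col_character(),
      timepoint_index = readr::col_integer(),
      reader_id = readr::col_character(),
      volume_cm3 = readr::col_double()
    )
  )
  validate_cohort(data)
  data
}

#' Write a cohort table to CSV
#'
#' @param data A cohort tibble (see [read_cohort_csv()] for the schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  validate_cohort(data[, cohort_columns])
  readr::write_csv(data[, cohort_columns], path)
  invisible(path)
}

#' Write an agreement report as JSON
#'
#' Serialises the summary of a [reader_agreement()] report (counts, fraction
#' within band, binomial CI, parameters) to a JSON file.
#'
#' @param report An `agreement_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement_json <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  jsonlite::write_json(
    as.list(report$summary),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
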