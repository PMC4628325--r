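#' Relative change of a measurement against a reference
#'
#' `(current - reference) / reference`, identical to the volume ratio minus
#' one; the quantity the response categories are defined on.
#'
#' @param reference_volume Reference volume(s) (> 0).
#' @param current_volume Current volume(s).
#' @return Signed fractional change(s).
#' @examples
#' relative_change(100, 65) # -0.35
#' @export
relative_change <- function(reference_volume, current_volume) {
  abort_if(any(reference_volume <= 0), "`reference_volume` must be positive")
  (current_volume - reference_volume) / reference_volume
}

cohort_columns <- c("patient_id", "lesion_id", "timepoint_index", "reader_id", "volume_cm3")

validate_cohort <- function(data) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(cohort_columns, names(data))
  abort_if(
    length(missing_cols) > 0,
    paste("cohort table is missing column(s):", paste(missing_cols, collapse = ", "))
  )
  abort_if(any(!is.finite(data$volume_cm3)) || any(data$volume_cm3 <= 0),
           "all volumes must be positive and finite")
  abort_if(any(data$timepoint_index < 0), "`timepoint_index` must be >= 0 (0 = baseline)")
  dup <- duplicated(data[, c("patient_id", "lesion_id", "timepoint_index", "reader_id")])
  abort_if(any(dup), "duplicated (patient, lesion, timepoint, reader) measurements")

  no_baseline <- data |>
    dplyr::summarise(
      has_baseline = any(.data$timepoint_index == 0),
      .by = c("patient_id", "lesion_id", "reader_id")
    ) |>
    dplyr::filter(!.data$has_baseline)
  if (nrow(no_baseline) > 0) {
    ids <- utils::head(
      paste(no_baseline$patient_id, no_baseline$lesion_id, no_baseline$reader_id, sep = "/"),
      5L
    )
    stop("series without a baseline (timepoint 0): ", paste(ids, collapse = ", "),
         if (nrow(no_baseline) > 5) " ..." else "", call. = FALSE)
  }
  invisible(data)
}

#' Classify longitudinal multi-reader lesion measurements
#'
#' Computes, for every reader's series and every post-baseline timepoint, the
#' relative volume change against the chosen reference and the PR/SD/PD
#' category. The two-way evaluation (`reference = "both"`, the default)
#' produces one assessment per reference mode, mirroring the design that
#' balances responding and progressive assessments: against `"baseline"`
#' (the reader's measurement at timepoint 0) and against `"nadir"` (the
#' reader's smallest measurement strictly before the current timepoint,
#' baseline included -- per reader, so each series is self-contained).
#'
#' @param data A cohort table with columns `patient_id`, `lesion_id`,
#'   `timepoint_index` (0 = baseline), `reader_id`, `volume_cm3`. Every
#'   (patient, lesion, reader) series must include a baseline.
#' @param reference `"both"` (default), `"baseline"` or `"nadir"`.
#' @param thresholds A [response_thresholds()] object used for the category.
#' @return A tibble with one row per (series, eligible timepoint, reference
#'   mode): the input keys plus `reference`, `reference_volume`,
#'   `volume_cm3`, `relative_change` and `category` (factor PR/SD/PD).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_patients = 2), seed = 1)
#' assessments <- assess_cohort(cohort$measurements)
#' dplyr::count(assessments, reference, category)
#' @export
assess_cohort <- function(data, reference = c("both", "baseline", "nadir"),
                          thresholds = response_thresholds()) {
  reference <- match.arg(reference)
  validate_cohort(data)
  th <- as_thresholds(thresholds)
  modes <- if (reference == "both") c("baseline", "nadir") else reference

  series <- data |>
    dplyr::arrange(.data$patient_id, .data$lesion_id, .data$reader_id, .data$timepoint_index)

  one_mode <- function(mode) {
    refd <- series |>
      dplyr::mutate(
        reference_volume = if (mode == "baseline") {
          .data$volume_cm3[.data$timepoint_index == 0][1]
        } else {
          # nadir: running minimum over strictly earlier timepoints
          dplyr::lag(cummin(.data$volume_cm3))
        },
        .by = c("patient_id", "lesion_id", "reader_id")
      ) |>
      dplyr::filter(.data$timepoint_index > 0)
    refd$reference <- mode
    refd
  }

  out <- dplyr::bind_rows(lapply(modes, one_mode))
  out$relative_change <- relative_change(out$reference_volume, out$volume_cm3)
  out$category <- classify_change(out$relative_change, th)
  out |>
    dplyr::select(dplyr::all_of(c(
      "patient_id", "lesion_id", "timepoint_index", "reader_id", "reference",
      "reference_volume", "volume_cm3", "relative_change", "category"
    ))) |>
    dplyr::arrange(.data$patient_id, .data$lesion_id, .data$reference,
                   .data$timepoint_index, .data$reader_id)
}

#' Nadir volume of one reader's series before a timepoint
#'
#' The smallest volume recorded strictly before timepoint `at` (baseline
#' included), the reference used for progression assessment.
#'
#' @param volumes Volumes of one reader's series.
#' @param timepoints Corresponding timepoint indices (0 = baseline).
#' @param at Timepoint (>= 1) whose reference is sought.
#' @return The nadir volume (cm^3).
#' @examples
#' nadir_volume(c(100, 80, 120), 0:2, at = 2) # 80
#' @export
nadir_volume <- function(volumes, timepoints, at) {
  abort_if(length(volumes) != length(timepoints), "`volumes` and `timepoints` must have equal length")
  abort_if(at < 1, "no reference exists before the baseline (`at` must be >= 1)")
  prior <- volumes[timepoints < at]
  abort_if(length(prior) == 0, "no timepoint before `at` in this series")
  min(prior)
}

#' Reader scattering against the model's predicted variability band
#'
#' Tests, for every (patient, lesion, timepoint, reference) group with at
#' least two readers, whether each reader's relative change falls inside the
#' variability band the ratio model predicts around the group's mean change:
#' the multiplicative confidence factors \eqn{A_L, A_U} (the critical ratios
#' of [response_thresholds()] at `(k, level)`) applied to `1 + m`, with `m`
#' the group-mean relative change, giving the band
#' `[(1 + m) A_L - 1, (1 + m) A_U - 1]`.
#'
#' @param assessments Output of [assess_cohort()] (or any tibble with the
#'   grouping columns and `relative_change`).
#' @param k Per-measurement coefficient of variation used for the band.
#' @param level Confidence level of the band.
#' @param leave_one_out If `TRUE`, the group mean anchoring the band for a
#'   reader excludes that reader's own assessment. Default `FALSE` (the
#'   group mean includes the reader under test).
#' @param min_readers Groups with fewer readers are excluded with a warning.
#' @return An object of class `agreement_report`: a list with `summary`
#'   (tibble: `n_assessments`, `n_within`, `fraction_within` and its exact
#'   binomial 95 % CI) and `assessments` (per-assessment tibble with the
#'   band bounds and a logical `within_band`), plus the parameters. `tidy()`
#'   returns the per-assessment table, `glance()` the one-row summary.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_patients = 3), seed = 1)
#' reader_agreement(assess_cohort(cohort$measurements))
#' @export
reader_agreement <- function(assessments, k = 0.3 / 1.96, level = 0.95,
                             leave_one_out = FALSE, min_readers = 2L) {
  needed <- c("patient_id", "lesion_id", "timepoint_index", "relative_change")
  stopifnot(is.data.frame(assessments), all(needed %in% names(assessments)))
  abort_if(k <= 0, "`k` must be positive")
  if (!"reference" %in% names(assessments)) assessments$reference <- "baseline"
  th <- response_thresholds(k, level)

  keys <- c("patient_id", "lesion_id", "timepoint_index", "reference")
  grouped <- assessments |>
    dplyr::mutate(
      n_readers = dplyr::n(),
      group_mean_change = if (leave_one_out) {
        (sum(.data$relative_change) - .data$relative_change) / (dplyr::n() - 1)
      } else {
        mean(.data$relative_change)
      },
      .by = dplyr::all_of(keys)
    )
  small <- grouped$n_readers < min_readers
  if (any(small)) {
    warning(sprintf(
      "%d assessment(s) in groups with fewer than %d readers excluded from the agreement test",
      sum(small), min_readers
    ), call. = FALSE)
    grouped <- grouped[!small, , drop = FALSE]
  }
  abort_if(nrow(grouped) == 0, "no group with enough readers to test agreement")

  grouped <- grouped |>
    dplyr::mutate(
      band_lower = (1 + .data$group_mean_change) * th$lower_ratio - 1,
      band_upper = (1 + .data$group_mean_change) * th$upper_ratio - 1,
      within_band = .data$relative_change >= .data$band_lower &
        .data$relative_change <= .data$band_upper
    )

  n <- nrow(grouped)
  n_within <- sum(grouped$within_band)
  ci <- stats::binom.test(n_within, n)$conf.int
  summary <- tibble::tibble(
    n_assessments = n,
    n_within = n_within,
    fraction_within = n_within / n,
    conf_low = ci[1],
    conf_high = ci[2],
    k = k,
    level = level
  )
  structure(
    list(summary = summary, assessments = grouped, k = k, level = level,
         leave_one_out = leave_one_out),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Reader agreement vs predicted variability band (k = %.4f, %.0f%% level)\n",
    x$k, 100 * x$level
  ))
  cat(sprintf(
    "  %d of %d assessments within band: %.1f%% [%.1f; %.1f]\n",
    s$n_within, s$n_assessments, 100 * s$fraction_within,
    100 * s$conf_low, 100 * s$conf_high
  ))
  invisible(x)
}

#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) x$assessments

#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) x$summary

#' Plot reader assessments against the predicted variability band
#'
#' Scatter of each reader's relative change against the group-mean change,
#' with the model's predicted band and the response thresholds overlaid.
#'
#' @param object An `agreement_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  th <- response_thresholds(object$k, object$level)
  rng <- range(object$assessments$group_mean_change)
  band <- tibble::tibble(m = seq(rng[1], rng[2], length.out = 50))
  band$lo <- (1 + band$m) * th$lower_ratio - 1
  band$hi <- (1 + band$m) * th$upper_ratio - 1
  ggplot2::ggplot(object$assessments,
                  ggplot2::aes(x = .data$group_mean_change, y = .data$relative_change)) +
    ggplot2::geom_line(data = band, ggplot2::aes(x = .data$m, y = .data$lo),
                       colour = "red", inherit.aes = FALSE) +
    ggplot2::geom_line(data = band, ggplot2::aes(x = .data$m, y = .data$hi),
                       colour = "red", inherit.aes = FALSE) +
    ggplot2::geom_vline(xintercept = c(th$lower_pct, th$upper_pct) / 100,
                        linetype = 3, colour = "blue") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$reader_id), alpha = 0.7) +
    ggplot2::labs(
      x = "group mean relative change", y = "reader relative change",
      colour = "reader",
      title = "Reader scattering vs predicted confidence band"
    ) +
    ggplot2::theme_minimal()
}
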