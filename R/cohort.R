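#' Specification of a synthetic multi-reader follow-up cohort
#'
#' Parameters of the generator emulating a retrospective NSCLC follow-up
#' study: 10 patients with one pulmonary target lesion each, a baseline plus
#' six follow-up CTs (about 70 timepoints in total), six readers measuring
#' every lesion at every timepoint, baseline volumes spanning roughly
#' 0.2-381 cm^3, and multiplicative per-measurement error with CV ~15 %.
#'
#' @param n_patients Number of patients (one target lesion each).
#' @param n_timepoints Timepoints per patient including baseline (>= 2).
#' @param n_readers Readers measuring every lesion at every timepoint.
#' @param k Per-measurement coefficient of variation of the multiplicative
#'   lognormal reader error (>= 0; 0 means error-free measurements).
#' @param volume_range Baseline true-volume range in cm^3; baselines are
#'   drawn log-uniformly so small and large lesions are both represented.
#' @param course_probs Named probabilities of the three true-trajectory
#'   courses `shrinking`, `growing`, `stable`; the default mixture yields a
#'   roughly balanced split of responding and progressive assessments under
#'   the two-way (baseline/nadir) evaluation.
#' @param step_ratio_means Named per-step geometric-mean true ratios for the
#'   three courses.
#' @param step_ratio_sdlog Log-scale SD of the per-step jitter around the
#'   course mean.
#' @return A validated object of class `cohort_spec`.
#' @examples
#' cohort_spec()
#' @export
cohort_spec <- function(n_patients = 10,
                        n_timepoints = 7,
                        n_readers = 6,
                        k = 0.3 / 1.96,
                        volume_range = c(0.195, 380.976),
                        course_probs = c(shrinking = 0.4, growing = 0.4, stable = 0.2),
                        step_ratio_means = c(shrinking = 0.75, growing = 1.35, stable = 1.0),
                        step_ratio_sdlog = 0.10) {
  abort_if(n_patients < 1 || n_timepoints < 2 || n_readers < 1,
           "counts must be >= 1 (and at least two timepoints)")
  abort_if(!is.numeric(k) || length(k) != 1L || k < 0, "`k` must be a single CV >= 0")
  abort_if(length(volume_range) != 2L || any(volume_range <= 0) ||
             volume_range[1] >= volume_range[2],
           "`volume_range` must be an increasing positive pair")
  courses <- c("shrinking", "growing", "stable")
  abort_if(!all(courses %in% names(course_probs)) || any(course_probs < 0) ||
             sum(course_probs) <= 0,
           "`course_probs` must name shrinking/growing/stable with non-negative weights")
  abort_if(!all(courses %in% names(step_ratio_means)) || any(step_ratio_means <= 0),
           "`step_ratio_means` must name shrinking/growing/stable with positive ratios")
  abort_if(step_ratio_sdlog < 0, "`step_ratio_sdlog` must be >= 0")
  structure(
    list(
      n_patients = as.integer(n_patients),
      n_timepoints = as.integer(n_timepoints),
      n_readers = as.integer(n_readers),
      k = k,
      volume_range = volume_range,
      course_probs = course_probs[courses] / sum(course_probs[courses]),
      step_ratio_means = step_ratio_means[courses],
      step_ratio_sdlog = step_ratio_sdlog
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort spec: %d patients x %d timepoints x %d readers, reader CV k = %.4f\n",
    x$n_patients, x$n_timepoints, x$n_readers, x$k
  ))
  cat(sprintf("  baseline volumes %.3g-%.3g cm^3 (log-uniform); courses %s\n",
              x$volume_range[1], x$volume_range[2],
              paste(sprintf("%s %.2f", names(x$course_probs), x$course_probs),
                    collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic multi-reader lesion-volume cohort
#'
#' Simulates true per-lesion volume trajectories and per-reader observed
#' volumes. Each observed volume is the true volume times an independent
#' multiplicative lognormal error with coefficient of variation `k`
#' (moment-matched: mean 1, so observations are unbiased on the volume
#' scale), keeping measurements positive across the whole volume range.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed; generation is deterministic given the
#'   seed.
#' @param thresholds Thresholds used to record the true response category in
#'   the ground truth (default [response_thresholds()]).
#' @return A list of class `synthetic_cohort` with two tibbles:
#'   * `measurements`: `patient_id`, `lesion_id`, `timepoint_index`,
#'     `reader_id`, `volume_cm3` -- the table the response pipeline reads;
#'   * `truth`: per (patient, lesion, timepoint) the `course`,
#'     `true_volume_cm3`, `true_ratio_vs_baseline` and `true_category`
#'     (PR/SD/PD vs baseline).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_patients = 2), seed = 1)
#' head(cohort$measurements)
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL,
                            thresholds = response_thresholds()) {
  stopifnot(inherits(spec, "cohort_spec"))
  th <- as_thresholds(thresholds)
  gen <- function() {
    courses <- sample(names(spec$course_probs), spec$n_patients,
                      replace = TRUE, prob = spec$course_probs)
    baseline <- exp(stats::runif(
      spec$n_patients,
      log(spec$volume_range[1]), log(spec$volume_range[2])
    ))
    truth <- purrr::map_dfr(seq_len(spec$n_patients), function(p) {
      n_steps <- spec$n_timepoints - 1L
      step <- spec$step_ratio_means[[courses[p]]] *
        stats::rlnorm(n_steps, meanlog = 0, sdlog = spec$step_ratio_sdlog)
      vols <- baseline[p] * cumprod(c(1, step))
      tibble::tibble(
        patient_id = sprintf("P%02d", p),
        lesion_id = "L1",
        timepoint_index = seq_len(spec$n_timepoints) - 1L,
        course = courses[p],
        true_volume_cm3 = vols,
        true_ratio_vs_baseline = vols / vols[1]
      )
    })
    truth$true_category <- classify_change(truth$true_ratio_vs_baseline - 1, th)

    measurements <- tidyr::expand_grid(
      truth[, c("patient_id", "lesion_id", "timepoint_index", "true_volume_cm3")],
      reader_id = sprintf("R%d", seq_len(spec$n_readers))
    )
    err <- if (spec$k == 0) {
      rep(1, nrow(measurements))
    } else {
      s2 <- log(1 + spec$k^2)
      stats::rlnorm(nrow(measurements), meanlog = -s2 / 2, sdlog = sqrt(s2))
    }
    measurements$volume_cm3 <- measurements$true_volume_cm3 * err
    measurements$true_volume_cm3 <- NULL
    list(measurements = measurements, truth = truth)
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  structure(
    c(out, list(spec = spec, seed = seed)),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d measurements (%d patients, %d timepoints, %d readers)\n",
    nrow(x$measurements), x$spec$n_patients, x$spec$n_timepoints, x$spec$n_readers
  ))
  invisible(x)
}
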