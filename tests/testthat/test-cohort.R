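test_that("the generator is deterministic and respects its spec", {
  spec <- cohort_spec()
  c1 <- simulate_cohort(spec, seed = 101)
  c2 <- simulate_cohort(spec, seed = 101)
  expect_identical(c1$measurements, c2$measurements)
  expect_identical(c1$truth, c2$truth)

  m <- c1$measurements
  expect_equal(nrow(m), 10 * 7 * 6)
  expect_true(all(m$volume_cm3 > 0))
  expect_equal(sort(unique(m$timepoint_index)), 0:6)
  expect_equal(dplyr::n_distinct(m$reader_id), 6)
  # baselines inside the configured range
  base <- c1$truth[c1$truth$timepoint_index == 0, ]
  expect_true(all(base$true_volume_cm3 >= 0.195 & base$true_volume_cm3 <= 380.976))
  # truth ratios start at 1
  expect_true(all(base$true_ratio_vs_baseline == 1))
})

test_that("zero measurement error reproduces the true volumes exactly", {
  co <- simulate_cohort(cohort_spec(n_patients = 3, k = 0), seed = 4)
  joined <- dplyr::left_join(
    co$measurements, co$truth,
    by = c("patient_id", "lesion_id", "timepoint_index")
  )
  expect_equal(joined$volume_cm3, joined$true_volume_cm3, tolerance = 1e-14)
  # and every reader agrees with the predicted band trivially
  rep0 <- reader_agreement(assess_cohort(co$measurements))
  expect_equal(rep0$summary$fraction_within, 1)
})

test_that("reader replicates recover the nominal measurement CV", {
  spec <- cohort_spec(n_patients = 4, n_timepoints = 3, n_readers = 400)
  co <- simulate_cohort(spec, seed = 12)
  cvs <- co$measurements |>
    dplyr::summarise(cv = sd(volume_cm3) / mean(volume_cm3),
                     .by = c("patient_id", "timepoint_index"))
  # each lesion/timepoint cell has 400 replicates: CV within ~3 SE of k
  se_cv <- spec$k / sqrt(2 * 400)
  expect_true(all(abs(cvs$cv - spec$k) < 4 * se_cv))
  expect_equal(mean(cvs$cv), spec$k, tolerance = 0.02)
})

test_that("trajectory courses shape the true categories", {
  co <- simulate_cohort(cohort_spec(n_patients = 40), seed = 9)
  truth_last <- co$truth[co$truth$timepoint_index == 6, ]
  # shrinking courses end responding, growing courses end progressive
  shrink <- truth_last[truth_last$course == "shrinking", ]
  grow <- truth_last[truth_last$course == "growing", ]
  expect_true(mean(shrink$true_category == "PR") > 0.9)
  expect_true(mean(grow$true_category == "PD") > 0.9)

  # recovered categories from error-free measurements match the truth
  co0 <- simulate_cohort(cohort_spec(n_patients = 10, k = 0), seed = 13)
  a <- assess_cohort(co0$measurements, reference = "baseline")
  joined <- dplyr::inner_join(
    a[a$reader_id == "R1", ],
    co0$truth,
    by = c("patient_id", "lesion_id", "timepoint_index")
  )
  expect_equal(as.character(joined$category), as.character(joined$true_category))
})

test_that("spec validation rejects impossible configurations", {
  expect_error(cohort_spec(n_patients = 0), ">= 1")
  expect_error(cohort_spec(volume_range = c(5, 2)), "increasing")
  expect_error(cohort_spec(k = -0.1), "CV")
  expect_error(cohort_spec(course_probs = c(shrinking = 1, growing = 1, wrong = 1)),
               "course_probs")
})
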