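test_that("draw_pairs honours the requested moments in every family", {
  n <- 2e5
  for (kind in c("normal", "lognormal", "uniform")) {
    m <- error_model(kind, k = k_default, mu1 = 100)
    pairs <- draw_pairs(m, ratio = 0.8, n = n, seed = 11)
    se_mean <- k_default * 100 / sqrt(n)
    expect_lt(abs(mean(pairs$x1) - 100), 3 * se_mean)
    expect_lt(abs(mean(pairs$x2) - 80), 3 * se_mean / 0.8)
    # empirical CV close to k (moment matching)
    expect_equal(sd(pairs$x1) / mean(pairs$x1), k_default, tolerance = 0.02)
    expect_equal(sd(pairs$x2) / mean(pairs$x2), k_default, tolerance = 0.02)
    expect_true(all(pairs$x1 > 0))
  }
})

test_that("draws are reproducible given a seed and leave the RNG alone", {
  m <- error_model("lognormal")
  a <- draw_pairs(m, 1.3, 100, seed = 5)
  b <- draw_pairs(m, 1.3, 100, seed = 5)
  expect_identical(a, b)
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(draw_pairs(m, 1, 10, seed = 7)); after <- runif(1)
  expect_identical(before, after)
})

test_that("rejection_rate counts ratios outside the stable band", {
  th <- response_thresholds()
  inside <- tibble::tibble(x1 = c(100, 100), x2 = c(100, 150))
  expect_equal(rejection_rate(inside, th), 0)
  mixed <- tibble::tibble(x1 = rep(100, 4), x2 = c(60, 100, 156, 66))
  expect_equal(rejection_rate(mixed, th), 0.5)
  # boundary ratios are not rejected
  onband <- tibble::tibble(x1 = c(1, 1), x2 = c(th$lower_ratio, th$upper_ratio))
  expect_equal(rejection_rate(onband, th), 0)
  expect_error(rejection_rate(tibble::tibble(x1 = -1, x2 = 1), th), "non-positive")
})

test_that("the study grid is deterministic, serializable and sane", {
  s1 <- run_simulation_study(models = "normal", ratios = c(1, 1.3),
                             n_samples = 2000, seed = 3)
  s2 <- run_simulation_study(models = "normal", ratios = c(1, 1.3),
                             n_samples = 2000, seed = 3)
  expect_identical(s1$rejection_rate, s2$rejection_rate)
  expect_named(s1, c("model", "ratio", "n", "rejection_rate", "se"))
  expect_true(all(s1$rejection_rate >= 0 & s1$rejection_rate <= 1))
  expect_equal(s1$se, sqrt(s1$rejection_rate * (1 - s1$rejection_rate) / 2000))

  # single-sample degenerate run
  s3 <- run_simulation_study(models = "uniform", ratios = 1, n_samples = 1, seed = 1)
  expect_true(s3$rejection_rate %in% c(0, 1))
})

test_that("rejection rates are scale invariant under constant CV", {
  a <- run_simulation_study(models = "normal", ratios = c(1, 0.65),
                            n_samples = 5000, mu1 = 1, seed = 17)
  b <- run_simulation_study(models = "normal", ratios = c(1, 0.65),
                            n_samples = 5000, mu1 = 350, seed = 17)
  expect_identical(a$rejection_rate, b$rejection_rate)
})

test_that("expected rejection never decreases as the true change grows", {
  s <- run_simulation_study(
    models = "normal", ratios = c(1, 1.2, 1.4, 1.6, 1.8),
    n_samples = 5e4, seed = 23
  )
  expect_true(all(diff(s$rejection_rate) > -0.005))
  s2 <- run_simulation_study(
    models = "normal", ratios = c(1, 0.9, 0.8, 0.7, 0.6),
    n_samples = 5e4, seed = 29
  )
  expect_true(all(diff(s2$rejection_rate) > -0.005))
})

test_that("type I error stays near the nominal level for all error models", {
  s <- run_simulation_study(ratios = 1, n_samples = 10000, seed = 31)
  # the three families bracket the nominal 5 % from below and above
  expect_true(all(s$rejection_rate > 0.03 & s$rejection_rate < 0.065))
})

test_that("keep_pairs retains the simulated scatter and autoplot works", {
  s <- run_simulation_study(models = "normal", ratios = 1, n_samples = 500,
                            seed = 2, keep_pairs = TRUE)
  expect_true("pairs" %in% names(s))
  expect_equal(nrow(s$pairs[[1]]), 500)
  expect_s3_class(autoplot(s), "ggplot")
})
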