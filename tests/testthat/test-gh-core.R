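test_that("gh_transform matches direct evaluation of the ratio deviate", {
  k <- k_default
  # w at the true ratio: numerator vanishes regardless of the statistics
  expect_equal(gh_transform(0.5, mu1 = 100, mu2 = 50,
                            sigma1 = k * 100, sigma2 = k * 50), 0)
  expect_equal(gh_transform(1, mu1 = 3, mu2 = 3,
                            sigma1 = 0.3, sigma2 = 0.3, rho = 0.4), 0)

  # frozen direct evaluation: w = 1.5543, mu1 = mu2 = 1, sigma = k, rho = 0
  # z = 0.5543 / (k * sqrt(1 + 1.5543^2)) = 1.959258...
  z <- gh_transform(1.5543, 1, 1, k, k)
  expect_equal(z, 0.5543 / (k * sqrt(1 + 1.5543^2)), tolerance = 1e-12)
  expect_equal(z, 1.9593, tolerance = 1e-4)
  # the corresponding two-sided p sits at the 95 % boundary
  expect_lt(abs(2 * (1 - pnorm(z)) - 0.05), 1e-3)

  # sign of z follows the sign of w * mu1 - mu2
  expect_gt(gh_transform(1, 1, 0.5, k, k * 0.5), 0)
  expect_lt(gh_transform(0.8, 1, 1, k, k), 0)

  # vectorised over w
  expect_length(gh_transform(c(0.8, 1, 1.2), 1, 1, k, k), 3L)
})

test_that("gh_transform rejects invalid inputs and degenerate variance", {
  expect_error(gh_transform(1, mu1 = -1, mu2 = 1, sigma1 = 0.1, sigma2 = 0.1),
               "mu1")
  expect_error(gh_transform(1, 1, 1, 0.1, 0.1, rho = 1.5), "rho")
  # rho = 1 with w = sigma2/sigma1 collapses the radicand to zero
  expect_error(
    suppressWarnings(gh_transform(1, 1, 1, 0.5, 0.5, rho = 1)),
    "non-positive variance"
  )
  # CVs outside (0.005, 0.39) warn but do not block
  expect_warning(gh_transform(1.2, 1, 1, 0.5, 0.5), "validity range")
  expect_warning(gh_transform(1.2, 1, 1, 0.001, 0.1), "validity range")
})

test_that("ratio_ci reproduces the symmetric worked example and degenerate cases", {
  k <- k_default
  ci <- ratio_ci(100, 100, c1 = k)
  expect_equal(ci$lower, 0.643288, tolerance = 1e-6)
  expect_equal(ci$upper, 1.554515, tolerance = 1e-6)
  expect_equal(ci$t, 1.96)
  # interval brackets the observed ratio
  expect_lt(ci$lower, 1)
  expect_gt(ci$upper, 1)

  # zero variance collapses to the point estimate
  ci0 <- ratio_ci(80, 120, c1 = 0, c2 = 0)
  expect_equal(ci0$lower, 1.5)
  expect_equal(ci0$upper, 1.5)

  # symmetric case identity: lower * upper = (x2/x1)^2 across a k grid
  for (kk in seq(0.02, 0.3, by = 0.04)) {
    ci <- ratio_ci(50, 70, c1 = kk)
    expect_equal(ci$lower * ci$upper, (70 / 50)^2, tolerance = 1e-12)
  }
})

test_that("general CI reduces to the simplified form when rho = 0, c1 = c2", {
  for (kk in c(0.05, 0.1, 0.2, 0.3)) {
    th <- response_thresholds(kk)
    ci <- ratio_ci(1, 1, c1 = kk, c2 = kk, rho = 0)
    expect_equal(ci$lower, th$lower_ratio, tolerance = 1e-12)
    expect_equal(ci$upper, th$upper_ratio, tolerance = 1e-12)
  }
  # and differs once correlation enters
  ci_rho <- ratio_ci(1, 1, c1 = 0.1, rho = 0.5)
  expect_false(isTRUE(all.equal(ci_rho$lower, response_thresholds(0.1)$lower_ratio)))
})

test_that("ratio_ci errors name the violated condition", {
  expect_error(ratio_ci(100, 100, c1 = 0.6, t = 1.96), "t \\* c2")
  expect_error(ratio_ci(-1, 100, c1 = 0.1), "positive volumes")
  # under t*c2 < 1 the radicand is provably non-negative (its minimum over
  # c1 is c2^2 (1 - rho^2/(1 - t^2 c2^2 (1 - rho^2))) >= 0), so only the
  # denominator condition is reachable; the radicand guard stays defensive
})

test_that("no-change rejection region equals the threshold band", {
  th <- response_thresholds()
  w <- seq(0.4, 1.8, by = 0.002)
  ci <- ratio_ci(rep(1, length(w)), w, c1 = k_default)
  rejected_by_ci <- ci$lower > 1 | ci$upper < 1
  outside_band <- w < th$lower_ratio | w > th$upper_ratio
  expect_equal(rejected_by_ci, outside_band)
})
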