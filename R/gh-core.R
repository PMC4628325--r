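#' Geary-Hinkley transformation of a volume ratio
#'
#' Maps the observed ratio `w = x2/x1` of two (approximately) bivariate-normal
#' measurements to an approximately standard-normal deviate,
#' \deqn{Z = (W\mu_1 - \mu_2) / \sqrt{\sigma_2^2 - 2W\rho\sigma_1\sigma_2 + W^2\sigma_1^2},}
#' the basis of every confidence interval, p-value and power computation in
#' this package.
#'
#' @param w Observed ratio(s) of follow-up to reference measurement
#'   (dimensionless, > 0). Vectorised.
#' @param mu1,mu2 Expected volumes at the reference and follow-up timepoints
#'   (same units, both > 0).
#' @param sigma1,sigma2 Measurement standard deviations at the two timepoints
#'   (>= 0).
#' @param rho Correlation between the two measurement errors, in \[-1, 1\].
#'   Defaults to 0 (independent measurement errors).
#'
#' @return A numeric vector of transformed deviates, the same length as `w`.
#'   The sign of the result equals the sign of `w * mu1 - mu2`.
#'
#' @details The coefficients of variation `sigma1/mu1` and `sigma2/mu2` are
#'   checked against the validity range (0.005, 0.39) of the normal
#'   approximation; values outside it raise a warning, never an error.
#'
#' @examples
#' gh_transform(1.2, mu1 = 100, mu2 = 100, sigma1 = 15, sigma2 = 15)
#' # vanishing numerator: the observed ratio equals the true ratio
#' gh_transform(0.5, mu1 = 100, mu2 = 50, sigma1 = 15, sigma2 = 7.5)
#' @export
gh_transform <- function(w, mu1, mu2, sigma1, sigma2, rho = 0) {
  stopifnot(is.numeric(w), length(w) >= 1L)
  abort_if(!is.numeric(mu1) || mu1 <= 0, "`mu1` must be a positive volume")
  abort_if(!is.numeric(mu2) || mu2 <= 0, "`mu2` must be a positive volume")
  abort_if(sigma1 < 0 || sigma2 < 0, "`sigma1` and `sigma2` must be >= 0")
  abort_if(abs(rho) > 1, "`rho` must lie in [-1, 1]")
  check_cv_validity(c(sigma1 / mu1, sigma2 / mu2), "sigma/mu")

  radicand <- sigma2^2 - 2 * w * rho * sigma1 * sigma2 + w^2 * sigma1^2
  if (any(radicand <= 0)) {
    off <- w[radicand <= 0][1L]
    stop(
      sprintf(
        "non-positive variance of (W*X1 - X2) at w = %g, rho = %g: the transformation is undefined for this combination",
        off, rho
      ),
      call. = FALSE
    )
  }
  (w * mu1 - mu2) / sqrt(radicand)
}

#' Confidence interval for the ratio of two measured volumes
#'
#' Inverts the Geary-Hinkley transformation to give the closed-form lower and
#' upper confidence limits for the true ratio \eqn{\mu_2/\mu_1} given one
#' observed pair of measurements, in the general form with possibly unequal
#' coefficients of variation and correlated errors:
#' \deqn{\frac{X_2}{X_1}\,\frac{1 - t^2\rho c_1 c_2 \mp t\sqrt{c_2^2 - 2\rho c_1 c_2 + c_1^2 - t^2 c_1^2 c_2^2 (1-\rho^2)}}{1 - t^2 c_2^2}.}
#'
#' @param x1,x2 Observed volumes at the reference and follow-up timepoints
#'   (> 0, same units). Vectorised (recycled together).
#' @param c1,c2 Coefficients of variation of the two measurements (`c2`
#'   defaults to `c1`).
#' @param rho Correlation between measurement errors (default 0).
#' @param level Two-sided confidence level in (0, 1); default 0.95.
#' @param t Optional explicit normal quantile overriding `level` (the 95 %
#'   worked examples in the field use 1.96 literally, which is also this
#'   package's behaviour at `level = 0.95`).
#'
#' @return A tibble with columns `estimate` (`x2/x1`), `lower`, `upper`,
#'   `level` and `t`, one row per observation pair.
#'
#' @details Requires `t * c2 < 1` (positive denominator) and a non-negative
#'   radicand; violations raise errors naming the condition. With `rho = 0`
#'   and `c1 = c2 = k` the limits reduce to the symmetric form used by
#'   [response_thresholds()], and `lower * upper = (x2/x1)^2` exactly.
#'
#' @examples
#' ratio_ci(100, 80, c1 = 0.3 / 1.96)
#' @export
ratio_ci <- function(x1, x2, c1, c2 = c1, rho = 0, level = 0.95, t = NULL) {
  abort_if(any(x1 <= 0) || any(x2 <= 0), "`x1` and `x2` must be positive volumes")
  abort_if(c1 < 0 || c2 < 0, "`c1` and `c2` must be >= 0")
  abort_if(abs(rho) > 1, "`rho` must lie in [-1, 1]")
  tq <- level_quantile(level, t)
  abort_if(
    tq * c2 >= 1,
    sprintf("t * c2 = %g >= 1: the denominator 1 - t^2 c2^2 is not positive and the interval is undefined", tq * c2)
  )
  radicand <- c2^2 - 2 * rho * c1 * c2 + c1^2 - tq^2 * c1^2 * c2^2 * (1 - rho^2)
  abort_if(
    radicand < 0,
    sprintf("negative radicand (%g) in the confidence-limit formula for rho = %g, c1 = %g, c2 = %g", radicand, rho, c1, c2)
  )

  ratio <- x2 / x1
  denom <- 1 - tq^2 * c2^2
  centre <- 1 - tq^2 * rho * c1 * c2
  half <- tq * sqrt(radicand)
  tibble::tibble(
    estimate = ratio,
    lower = ratio * (centre - half) / denom,
    upper = ratio * (centre + half) / denom,
    level = level,
    t = tq
  )
}
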