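#' Symmetric response thresholds from measurement variability
#'
#' Derives the pair of critical volume ratios bounding stable disease when
#' both timepoints share the same measurement coefficient of variation `k`
#' and the errors are uncorrelated. The confidence limits then simplify to
#' \deqn{\frac{1 \mp t\sqrt{2k^2 - t^2 k^4}}{1 - t^2 k^2},}
#' whose lower/upper values are the largest significant decrease and smallest
#' significant increase of the no-change test. At the default
#' `k = 0.3/1.96` (the 15 % repeatability of CT tumour volumetry reported by
#' QIBA) and the 95 % level these are approximately 0.643 and 1.554.
#'
#' @param k Coefficient of variation of a single volume measurement (> 0).
#'   Default `0.3/1.96` (~= 0.1531).
#' @param level Two-sided confidence level, default 0.95.
#' @param t Optional explicit normal quantile; by default 1.96 literally at
#'   `level = 0.95`, the exact quantile otherwise.
#'
#' @return An object of class `vol_thresholds`: a list with elements
#'   `lower_ratio`, `upper_ratio` (unrounded critical ratios), `lower_pct`,
#'   `upper_pct` (signed integer percent change, rounded half away from
#'   zero), `k`, `level` and `t`.
#'
#' @details The critical ratios are reciprocal: `lower_ratio * upper_ratio`
#'   equals 1 exactly (algebraically, since
#'   \eqn{1 - t^2(2k^2 - t^2k^4) = (1 - t^2k^2)^2}). Statistical tests use
#'   the unrounded ratios; the integer percent fields are the presentation /
#'   clinical-reporting form. Note that at the default `k` the lower critical
#'   ratio 0.6433 is a 35.7 % decrease, i.e. -36 % after integer rounding;
#'   the commonly quoted "-35 %" arises from first rounding the ratio to
#'   0.65.
#'
#' @examples
#' response_thresholds()
#' response_thresholds(k = 0.05)
#' @seealso [classify_ratio()], [gh_power()], [diameter_thresholds()]
#' @export
response_thresholds <- function(k = 0.3 / 1.96, level = 0.95, t = NULL) {
  abort_if(!is.numeric(k) || length(k) != 1L || k <= 0, "`k` must be a single positive coefficient of variation")
  tq <- level_quantile(level, t)
  abort_if(
    tq * k >= 1,
    sprintf("t * k = %g >= 1: thresholds are undefined (denominator 1 - t^2 k^2 <= 0)", tq * k)
  )
  half <- tq * sqrt(2 * k^2 - tq^2 * k^4)
  denom <- 1 - tq^2 * k^2
  lower <- (1 - half) / denom
  upper <- (1 + half) / denom
  structure(
    list(
      lower_ratio = lower,
      upper_ratio = upper,
      lower_pct = as.integer(round_half_out(100 * (lower - 1))),
      upper_pct = as.integer(round_half_out(100 * (upper - 1))),
      k = k,
      level = level,
      t = tq
    ),
    class = "vol_thresholds"
  )
}

#' @export
print.vol_thresholds <- function(x, ...) {
  cat(sprintf(
    "Volumetric response thresholds (CV k = %.4f, %.0f%% level, t = %.4g)\n",
    x$k, 100 * x$level, x$t
  ))
  cat(sprintf(
    "  decrease (PR) below ratio %.4f (%+d%%)\n", x$lower_ratio, x$lower_pct
  ))
  cat(sprintf(
    "  increase (PD) above ratio %.4f (%+d%%)\n", x$upper_ratio, x$upper_pct
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy vol_thresholds
#' @export
tidy.vol_thresholds <- function(x, ...) {
  tibble::tibble(
    boundary = c("lower", "upper"),
    ratio = c(x$lower_ratio, x$upper_ratio),
    pct_change = c(x$lower_pct, x$upper_pct),
    k = x$k,
    level = x$level,
    t = x$t
  )
}

#' @method glance vol_thresholds
#' @export
glance.vol_thresholds <- function(x, ...) {
  tibble::tibble(
    lower_ratio = x$lower_ratio,
    upper_ratio = x$upper_ratio,
    lower_pct = x$lower_pct,
    upper_pct = x$upper_pct,
    k = x$k,
    level = x$level,
    t = x$t
  )
}

as_thresholds <- function(thresholds) {
  if (inherits(thresholds, "vol_thresholds")) return(thresholds)
  if (is.numeric(thresholds) && length(thresholds) == 2L) {
    abort_if(
      !(0 < thresholds[1] && thresholds[1] < 1 && thresholds[2] > 1),
      "numeric thresholds must be a (lower, upper) ratio pair with lower < 1 < upper"
    )
    return(structure(
      list(
        lower_ratio = thresholds[1], upper_ratio = thresholds[2],
        lower_pct = as.integer(round_half_out(100 * (thresholds[1] - 1))),
        upper_pct = as.integer(round_half_out(100 * (thresholds[2] - 1))),
        k = NA_real_, level = NA_real_, t = NA_real_
      ),
      class = "vol_thresholds"
    ))
  }
  stop("`thresholds` must be a `vol_thresholds` object or a (lower, upper) ratio pair", call. = FALSE)
}
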