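#' P-value of the no-change test for an observed volume ratio
#'
#' Two-sided p-value for the null hypothesis that the true volume ratio is 1,
#' under equal coefficients of variation `k` at both timepoints and
#' uncorrelated errors. The transformed statistic reduces to
#' \deqn{z_0 = (w - 1) / (k\sqrt{1 + w^2})}
#' and `p = 2 * (1 - pnorm(|z0|))`.
#'
#' @param w Observed volume ratio(s) (> 0). Vectorised.
#' @param k Per-measurement coefficient of variation (> 0), default
#'   `0.3/1.96`.
#'
#' @return Numeric vector of p-values in (0, 1]; exactly 1 at `w = 1`, and
#'   equal to the test size at the unrounded critical ratios of
#'   [response_thresholds()].
#' @examples
#' gh_pvalue(c(0.8, 1, 1.5543))
#' @export
gh_pvalue <- function(w, k = 0.3 / 1.96) {
  abort_if(any(w <= 0), "`w` must be a positive ratio")
  abort_if(k <= 0, "`k` must be positive")
  z0 <- (w - 1) / (k * sqrt(1 + w^2))
  2 * (1 - stats::pnorm(abs(z0)))
}

#' Statistical power of the no-change test at a known true ratio
#'
#' Probability that an observed ratio falls outside the stable band when the
#' true volume ratio is `r`, i.e. the probability of declaring change:
#' \deqn{\mathrm{power}(r) = \Phi(z(w_L; r)) + 1 - \Phi(z(w_U; r)),}
#' where \eqn{w_L, w_U} are the (unrounded) critical ratios and
#' \eqn{z(w; r) = (w - r)/(k\sqrt{r^2 + w^2})} is the transformed deviate
#' with \eqn{\mu_2 = r\mu_1} and \eqn{\sigma_i = k\mu_i}.
#'
#' @param r True volume ratio(s) (> 0). Vectorised.
#' @param k Per-measurement coefficient of variation (> 0).
#' @param thresholds A [response_thresholds()] object (or `(lower, upper)`
#'   ratio pair) defining the rejection region; defaults to the thresholds
#'   implied by `k` and `level`.
#' @param level Confidence level used when `thresholds` is not supplied.
#'
#' @return Numeric vector of probabilities. At `r = 1` the power equals the
#'   size of the test (~= `1 - level`); it approaches 0.5 when `r` sits on a
#'   boundary.
#' @examples
#' gh_power(c(0.5, 0.8, 1.3, 1.8))
#' @export
gh_power <- function(r, k = 0.3 / 1.96, thresholds = NULL, level = 0.95) {
  abort_if(any(r <= 0), "`r` must be a positive ratio")
  abort_if(k <= 0, "`k` must be positive")
  th <- if (is.null(thresholds)) response_thresholds(k, level) else as_thresholds(thresholds)
  z_at <- function(w) (w - r) / (k * sqrt(r^2 + w^2))
  stats::pnorm(z_at(th$lower_ratio)) + 1 - stats::pnorm(z_at(th$upper_ratio))
}

#' P-value and power over a grid of volume ratios
#'
#' Convenience wrapper evaluating [gh_pvalue()] and [gh_power()] on a ratio
#' grid, the tabular analogue of the p-value/power curve figure.
#'
#' @param k Per-measurement coefficient of variation.
#' @param ratios Grid of ratios; default `seq(0.4, 1.8, by = 0.005)`.
#' @param level Confidence level.
#' @return A tibble with columns `ratio`, `p_value`, `power`.
#' @examples
#' power_curve(ratios = c(0.5, 1, 1.3))
#' @export
power_curve <- function(k = 0.3 / 1.96, ratios = seq(0.4, 1.8, by = 0.005),
                        level = 0.95) {
  th <- response_thresholds(k, level)
  tibble::tibble(
    ratio = ratios,
    p_value = gh_pvalue(ratios, k),
    power = gh_power(ratios, k, thresholds = th)
  )
}

#' Plot the p-value and power curves of the no-change test
#'
#' @param data A tibble from [power_curve()].
#' @return A ggplot object with the two curves against the true/observed
#'   ratio, with the critical ratios implied by the curve minimum marked.
#' @export
plot_power_curve <- function(data) {
  stopifnot(all(c("ratio", "p_value", "power") %in% names(data)))
  long <- tidyr::pivot_longer(
    data, c("p_value", "power"),
    names_to = "curve", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ratio, y = .data$value,
                                     colour = .data$curve, linetype = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(p_value = "grey20", power = "firebrick")) +
    ggplot2::labs(
      x = "volume ratio (follow-up / reference)",
      y = "probability",
      colour = NULL, linetype = NULL,
      title = "No-change test: p-value and statistical power"
    ) +
    ggplot2::theme_minimal()
}

#' Classify an observed volume ratio against response thresholds
#'
#' @param w Observed volume ratio(s) (> 0).
#' @param thresholds A [response_thresholds()] object or `(lower, upper)`
#'   ratio pair.
#' @param labels Length-3 category labels for (significant decrease, no
#'   change, significant increase); default `c("decrease", "no-change",
#'   "increase")`. Use `c("PR", "SD", "PD")` for clinical response labels
#'   (see [classify_change()]).
#' @return A factor with the three category levels. Values exactly on a
#'   boundary are classified as no change (rejection requires strict
#'   exclusion of 1 from the open confidence interval).
#' @examples
#' classify_ratio(c(0.6, 1, 1.55, 1.6), response_thresholds())
#' @export
classify_ratio <- function(w, thresholds = response_thresholds(),
                           labels = c("decrease", "no-change", "increase")) {
  abort_if(any(!is.finite(w)) || any(w <= 0), "`w` must be a positive ratio")
  stopifnot(length(labels) == 3L)
  th <- as_thresholds(thresholds)
  out <- ifelse(w < th$lower_ratio, labels[1L],
         ifelse(w > th$upper_ratio, labels[3L], labels[2L]))
  factor(out, levels = labels)
}

#' Classify a relative volume change as PR / SD / PD
#'
#' Clinical counterpart of [classify_ratio()] operating on signed relative
#' changes `(x2 - x1)/x1`: partial response below the lower threshold,
#' progressive disease above the upper one, stable disease between
#' (boundaries included).
#'
#' @param change Signed relative change(s), each > -1.
#' @param thresholds A [response_thresholds()] object or ratio pair.
#' @param boundaries Which form of the thresholds bounds the stable region:
#'   `"percent"` (default) uses the integer percent fields, the clinical
#'   reporting convention; `"ratio"` uses the unrounded critical ratios, the
#'   statistical test's rejection region.
#' @return Factor with levels `PR`, `SD`, `PD`.
#' @examples
#' classify_change(c(-0.4, 0, 0.6))
#' @export
classify_change <- function(change, thresholds = response_thresholds(),
                            boundaries = c("percent", "ratio")) {
  abort_if(any(change <= -1), "`change` must exceed -1 (volumes are positive)")
  boundaries <- match.arg(boundaries)
  th <- as_thresholds(thresholds)
  if (boundaries == "percent") {
    th <- as_thresholds(1 + c(th$lower_pct, th$upper_pct) / 100)
  }
  classify_ratio(1 + change, th, labels = c("PR", "SD", "PD"))
}
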