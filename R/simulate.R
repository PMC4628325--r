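#' Specify a measurement-error model for simulation
#'
#' @param kind Distribution family of a single volume measurement: `"normal"`
#'   (mean `mu`, SD `k * mu`), `"lognormal"` (moment-matched: log-scale
#'   variance `log(1 + k^2)`, so the mean is `mu` and the CV is `k`), or
#'   `"uniform"` (on `mu * (1 - sqrt(3) k)` to `mu * (1 + sqrt(3) k)`,
#'   matching mean and SD).
#' @param k Coefficient of variation of a single measurement (> 0).
#' @param mu1 Baseline mean volume in cm^3 (> 0). Rejection rates are scale
#'   invariant under the constant-CV assumption; the default 100 cm^3 is a
#'   typical lung-lesion volume.
#' @return An object of class `error_model`.
#' @examples
#' error_model("lognormal")
#' @export
error_model <- function(kind = c("normal", "lognormal", "uniform"),
                        k = 0.3 / 1.96, mu1 = 100) {
  kind <- match.arg(kind)
  abort_if(!is.numeric(k) || length(k) != 1L || k <= 0, "`k` must be a single positive CV")
  abort_if(!is.numeric(mu1) || length(mu1) != 1L || mu1 <= 0, "`mu1` must be a single positive volume")
  structure(list(kind = kind, k = k, mu1 = mu1), class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("Measurement error model: %s, CV k = %.4f, baseline mean %.3g cm^3\n",
              x$kind, x$k, x$mu1))
  invisible(x)
}

# one vector of measurements with mean mu and CV k under the model family
draw_measurements <- function(kind, n, mu, k) {
  switch(kind,
    normal = stats::rnorm(n, mean = mu, sd = k * mu),
    lognormal = {
      s2 <- log(1 + k^2)
      stats::rlnorm(n, meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
    },
    uniform = {
      h <- sqrt(3) * k
      stats::runif(n, min = mu * (1 - h), max = mu * (1 + h))
    }
  )
}

#' Draw paired baseline / follow-up volume measurements
#'
#' Simulates `n` independent pairs `(x1, x2)` where `x1` has mean `mu1` and
#' `x2` has mean `ratio * mu1`, both with constant coefficient of variation
#' `k` under the model's distribution family.
#'
#' @param model An [error_model()].
#' @param ratio True volume ratio between the two timepoints (> 0).
#' @param n Number of pairs (>= 1).
#' @param seed Optional integer seed; when given, draws are made in a local
#'   RNG scope and are reproducible without touching the caller's RNG state.
#' @return A tibble with columns `x1`, `x2`.
#' @details Under the normal model, baseline draws `x1 <= 0` (probability
#'   ~`pnorm(-1/k)`, about 3e-11 at the default CV) are redrawn so the ratio
#'   is always defined; follow-up draws are kept as-is.
#' @examples
#' draw_pairs(error_model("normal"), ratio = 1, n = 5, seed = 1)
#' @export
draw_pairs <- function(model, ratio, n, seed = NULL) {
  stopifnot(inherits(model, "error_model"))
  abort_if(!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0, "`ratio` must be a single positive number")
  abort_if(!is.numeric(n) || length(n) != 1L || n < 1, "`n` must be >= 1")
  draw <- function() {
    x1 <- draw_measurements(model$kind, n, model$mu1, model$k)
    # keep the ratio defined: baseline must be positive (normal model only)
    for (i in seq_len(100L)) {
      bad <- x1 <= 0
      if (!any(bad)) break
      x1[bad] <- draw_measurements(model$kind, sum(bad), model$mu1, model$k)
    }
    x2 <- draw_measurements(model$kind, n, ratio * model$mu1, model$k)
    tibble::tibble(x1 = x1, x2 = x2)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Fraction of simulated pairs rejecting the no-change hypothesis
#'
#' @param pairs A data frame with columns `x1`, `x2` (e.g. from
#'   [draw_pairs()]).
#' @param thresholds A [response_thresholds()] object or `(lower, upper)`
#'   ratio pair bounding the stable band.
#' @return The fraction of pairs whose ratio `x2/x1` falls strictly outside
#'   `[lower_ratio, upper_ratio]`.
#' @examples
#' rejection_rate(draw_pairs(error_model(), 1, 1000, seed = 1),
#'                response_thresholds())
#' @export
rejection_rate <- function(pairs, thresholds = response_thresholds()) {
  stopifnot(is.data.frame(pairs), all(c("x1", "x2") %in% names(pairs)), nrow(pairs) >= 1L)
  abort_if(any(pairs$x1 <= 0), "non-positive baseline measurement: the ratio is undefined")
  th <- as_thresholds(thresholds)
  w <- pairs$x2 / pairs$x1
  mean(w < th$lower_ratio | w > th$upper_ratio)
}

#' Monte Carlo robustness study of the response thresholds
#'
#' Simulates the full error-model-by-true-ratio grid and reports the
#' rejection rate of the no-change test in each cell: the type I error at
#' ratio 1, the empirical power elsewhere. This is the numerical twin of the
#' scatter-plot validation study (10,000 pairs per cell; normal, lognormal
#' and uniform error models; true ratios 1, 0.65, 1.55, 1.30).
#'
#' @param models Character vector of error-model kinds.
#' @param ratios True volume ratios to simulate.
#' @param n_samples Pairs per cell (default 10,000).
#' @param k Per-measurement coefficient of variation.
#' @param mu1 Baseline mean volume (cm^3).
#' @param level Confidence level of the test.
#' @param thresholds Stable-band boundaries used for rejection; defaults to
#'   the unrounded critical ratios implied by `k` and `level`.
#' @param seed Optional integer seed making the whole grid reproducible.
#' @param keep_pairs If `TRUE`, the simulated pairs are attached as a
#'   list-column `pairs` (for scatter plots).
#' @return A tibble of class `vol_simulation` with columns `model`, `ratio`,
#'   `n`, `rejection_rate` and `se` (the binomial Monte Carlo standard error
#'   `sqrt(p(1-p)/n)`), plus `pairs` when requested. The thresholds and seed
#'   are stored as attributes.
#' @examples
#' run_simulation_study(models = "normal", ratios = c(1, 1.3),
#'                      n_samples = 2000, seed = 1)
#' @export
run_simulation_study <- function(models = c("normal", "lognormal", "uniform"),
                                 ratios = c(1.0, 0.65, 1.55, 1.30),
                                 n_samples = 10000,
                                 k = 0.3 / 1.96,
                                 mu1 = 100,
                                 level = 0.95,
                                 thresholds = NULL,
                                 seed = NULL,
                                 keep_pairs = FALSE) {
  models <- match.arg(models, c("normal", "lognormal", "uniform"), several.ok = TRUE)
  abort_if(any(ratios <= 0), "`ratios` must all be positive")
  abort_if(n_samples < 1, "`n_samples` must be >= 1")
  th <- if (is.null(thresholds)) response_thresholds(k, level) else as_thresholds(thresholds)

  grid <- tidyr::expand_grid(model = models, ratio = ratios)
  run_grid <- function() {
    purrr::pmap(grid, function(model, ratio) {
      pairs <- draw_pairs(error_model(model, k = k, mu1 = mu1), ratio, n_samples)
      p <- rejection_rate(pairs, th)
      tibble::tibble(
        rejection_rate = p,
        se = sqrt(p * (1 - p) / n_samples),
        pairs = if (keep_pairs) list(pairs) else list(NULL)
      )
    })
  }
  cells <- if (is.null(seed)) run_grid() else withr::with_seed(seed, run_grid())

  out <- dplyr::bind_cols(grid, dplyr::bind_rows(cells))
  out$n <- n_samples
  out <- out[, c("model", "ratio", "n", "rejection_rate", "se", "pairs")]
  if (!keep_pairs) out$pairs <- NULL
  class(out) <- c("vol_simulation", class(out))
  attr(out, "thresholds") <- th
  attr(out, "seed") <- seed
  attr(out, "k") <- k
  out
}

#' @method autoplot vol_simulation
#' @export
autoplot.vol_simulation <- function(object, ...) {
  th <- attr(object, "thresholds")
  k <- attr(object, "k")
  analytic <- tibble::tibble(
    ratio = seq(min(object$ratio) * 0.9, max(object$ratio) * 1.1, length.out = 201)
  )
  analytic$power <- gh_power(analytic$ratio, k = k, thresholds = th)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ratio, y = .data$rejection_rate,
                                       colour = .data$model)) +
    ggplot2::geom_line(
      data = analytic,
      ggplot2::aes(x = .data$ratio, y = .data$power),
      inherit.aes = FALSE, colour = "grey60", linetype = 2
    ) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$rejection_rate - 3 * .data$se,
      ymax = .data$rejection_rate + 3 * .data$se
    ), position = ggplot2::position_dodge(width = 0.02)) +
    ggplot2::labs(
      x = "true volume ratio", y = "rejection rate",
      colour = "error model",
      title = "Monte Carlo rejection rates vs analytic power (dashed)"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
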