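# internal helpers shared across modules

# Round half away from zero (round() is banker's rounding, which would send
# e.g. +14.5 to 14). Threshold percents are presented with this convention.
round_half_out <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Normal quantile for a two-sided level. The canonical worked examples use
# t = 1.96 literally at the 95 % level, so that value is hard-coded there;
# any other level uses the exact quantile.
level_quantile <- function(level, t = NULL) {
  if (!is.null(t)) {
    stopifnot(is.numeric(t), length(t) == 1L, t > 0)
    return(t)
  }
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  if (isTRUE(all.equal(level, 0.95))) 1.96 else stats::qnorm(1 - (1 - level) / 2)
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

# The standard-normal approximation to the transformed ratio is only accurate
# for CVs in a bounded range; outside it we warn but never block.
check_cv_validity <- function(cv, label) {
  bad <- cv <= 0.005 | cv >= 0.39
  if (any(bad)) {
    warning(
      sprintf(
        "coefficient of variation %s = %s outside the validity range (0.005, 0.39) of the normal approximation; results may be unreliable",
        label, paste(signif(cv[bad], 4), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  invisible(!any(bad))
}
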