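# Internal helpers shared across modules.

# Condition labels in increasing stimulus-strength order.
.conditionLevels <- function(mode = c("duration", "pressure")) {
  mode <- match.arg(mode)
  if (mode == "duration") c("d1", "d2", "d3", "d4") else c("p1", "p2")
}

.allConditionLevels <- function() c("d1", "d2", "d3", "d4", "p1", "p2")

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Trapezoidal integral of y sampled at x.
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Median absolute deviation from the median, unscaled (the jitter measure).
jitterMad <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(abs(x - stats::median(x)))
}

# Centered rolling quantile with edge-truncated windows.
.rollQuantile <- function(x, width, prob) {
  n <- length(x)
  half <- (width - 1L) %/% 2L
  halfR <- width - 1L - half
  vapply(seq_len(n), function(i) {
    stats::quantile(x[max(1L, i - half):min(n, i + halfR)], prob,
                    names = FALSE, type = 7)
  }, numeric(1))
}

# Robust noise SD estimate from first differences (MAD-based; the factor
# sqrt(2) removes the variance doubling of differencing).
.robustNoiseSd <- function(x) {
  stats::mad(diff(x)) / sqrt(2)
}

.assertScalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  invisible(TRUE)
}
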