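# Calcium transient kernels.
#
# The CF event kernel is k(t) = (1 - exp(-t/tau_r)) * exp(-t * ln2 / t_half),
# normalised to unit peak, with tau_r chosen so the peak occurs at the
# requested time-to-peak. The slow non-CF component uses an alpha function
# g(t) = (t/tp) * exp(1 - t/tp), which peaks at tp with unit amplitude.

#' CF calcium-event kernel parameters
#'
#' Solves the rise time constant of the double-exponential climbing-fiber
#' event kernel so that its peak occurs at \code{riseMs}, and returns the
#' constants needed to evaluate and integrate the unit-peak kernel.
#'
#' @param riseMs time to peak in ms.
#' @param decayHalfMs half-decay time measured from the peak, ms (the
#'   quantity reported for CF transients); the underlying exponential's
#'   half-time is solved to be slightly shorter because the rise term keeps
#'   growing past the peak.
#' @return A list with elements \code{tauR}, \code{lambda}, \code{peakT}
#'   (= \code{riseMs}) and \code{peakVal} (peak of the unnormalised kernel).
#' @keywords internal
cfKernelParams <- function(riseMs = 10, decayHalfMs = 74) {
  .assertScalar(riseMs, "riseMs")
  .assertScalar(decayHalfMs, "decayHalfMs")
  lambda <- log(2) / decayHalfMs
  tauR <- riseMs / 3
  for (i in 1:8) {
    # peak time t* = tauR * log(1 + 1/(lambda*tauR)); monotone in tauR
    f <- function(tauR) tauR * log1p(1 / (lambda * tauR)) - riseMs
    tauR <- stats::uniroot(f, c(riseMs * 1e-4, riseMs * 20), tol = 1e-12)$root
    # lambda so that k(riseMs + decayHalfMs) = k(riseMs) / 2
    g <- (1 - exp(-(riseMs + decayHalfMs) / tauR)) / (1 - exp(-riseMs / tauR))
    lambda <- (log(g) + log(2)) / decayHalfMs
  }
  peakVal <- (1 - exp(-riseMs / tauR)) * exp(-lambda * riseMs)
  list(tauR = tauR, lambda = lambda, peakT = riseMs, peakVal = peakVal)
}

#' Evaluate the unit-peak CF kernel
#'
#' @param t times in ms (kernel starts at 0; values for t < 0 are 0).
#' @param params result of [cfKernelParams()].
#' @return numeric vector of kernel values, peak value 1 at \code{params$peakT}.
#' @keywords internal
cfKernel <- function(t, params) {
  out <- numeric(length(t))
  ok <- t >= 0
  tt <- t[ok]
  out[ok] <- (1 - exp(-tt / params$tauR)) * exp(-params$lambda * tt) / params$peakVal
  out
}

# Analytic integral of the unit-peak CF kernel over [a, b] (ms).
cfKernelIntegral <- function(a, b, params) {
  prim <- function(t) {
    # integral of (1 - exp(-t/tauR)) exp(-lambda t)
    mu <- params$lambda + 1 / params$tauR
    -exp(-params$lambda * t) / params$lambda + exp(-mu * t) / mu
  }
  a <- max(a, 0)
  if (b <= a) return(0)
  (prim(b) - prim(a)) / params$peakVal
}

# Alpha-function kernel, unit peak at tp (ms); 0 for t < 0.
alphaKernel <- function(t, tp) {
  out <- numeric(length(t))
  ok <- t >= 0
  u <- t[ok] / tp
  out[ok] <- u * exp(1 - u)
  out
}

# Analytic integral of the unit-peak alpha kernel over [a, b] (ms).
alphaKernelIntegral <- function(a, b, tp) {
  prim <- function(t) {
    u <- t / tp
    -tp * (u + 1) * exp(1 - u)
  }
  a <- max(a, 0)
  if (b <= a) return(0)
  prim(b) - prim(a)
}
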