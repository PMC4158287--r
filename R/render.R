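# Rendering ground truth to fluorescence.

#' Construct a CalciumExperiment
#'
#' @param dff dendrite x time matrix of dF/F values (or NULL).
#' @param F dendrite x time matrix of raw fluorescence (or NULL).
#' @param positionUm mediolateral ROI position per dendrite, um.
#' @param samplePeriodMs sample period of the columns, ms.
#' @param framePeriodMs acquisition frame period, ms.
#' @param protocol,truth,config optional provenance objects stored in
#'   metadata.
#' @return a \linkS4class{CalciumExperiment}.
#' @export
CalciumExperiment <- function(dff = NULL, F = NULL, positionUm = NULL,
                              samplePeriodMs, framePeriodMs = samplePeriodMs,
                              protocol = NULL, truth = NULL, config = NULL) {
  assays <- list()
  if (!is.null(F)) assays$F <- F
  if (!is.null(dff)) assays$dff <- dff
  if (!length(assays)) stop("need at least one of 'dff' or 'F'")
  n <- nrow(assays[[1]])
  if (is.null(positionUm)) positionUm <- rep(NA_real_, n)
  rd <- DataFrame(dendrite_id = seq_len(n), position_um = positionUm)
  rownames(rd) <- paste0("den", seq_len(n))
  se <- SummarizedExperiment(assays = assays, rowData = rd)
  md <- list(sample_period_ms = samplePeriodMs,
             frame_period_ms = framePeriodMs,
             protocol = protocol, truth = truth, config = config)
  se@metadata <- md
  new("CalciumExperiment", se)
}

# Sample times (ms, start-of-sample convention) of a CalciumExperiment.
#' @rdname CalciumExperiment
#' @param x a \linkS4class{CalciumExperiment}.
#' @export
sampleTimes <- function(x) {
  (seq_len(ncol(x)) - 1L) * samplePeriod(x)
}

#' Render ground-truth activity to fluorescence traces
#'
#' Each CF event contributes a unit-peak kernel
#' \code{(1 - exp(-t/tau_r)) exp(-t ln2 / t_half)} scaled by
#' \code{eventAmp} and the event's amplitude factor; each stimulated trial
#' additionally receives a slow non-CF alpha-function transient whose
#' time-to-peak and normalized dF/F-integral follow the trial's condition.
#' Components sum linearly; Gaussian noise of SD \code{noiseSd} is added at
#' the rendering resolution. The raw-fluorescence assay is
#' \code{F = f0 (1 + dF/F)}.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param config a \linkS4class{GeneratorConfig}.
#' @param protocol the \linkS4class{StimulusProtocol} used for simulation.
#' @param resolution sample period in ms (defaults to
#'   \code{config@renderResolution}; use \code{config@framePeriod} for
#'   frame-resolution rendering).
#' @param noise logical; add recording noise?
#' @param seed optional seed overriding \code{config@seed}.
#' @return a \linkS4class{CalciumExperiment} with assays \code{dff} and
#'   \code{F}.
#' @export
renderTraces <- function(truth, config, protocol,
                         resolution = config@renderResolution,
                         noise = TRUE, seed = NULL) {
  stopifnot(is(truth, "GroundTruth"), is(config, "GeneratorConfig"))
  if (is.null(seed)) seed <- config@seed
  n <- length(truth@roiPositions)
  durMs <- .recordingDuration(protocol, config) * 1000
  times <- seq(0, durMs - resolution / 2, by = resolution)
  nt <- length(times)
  params <- cfKernelParams(config@kernelRise, config@kernelDecayHalf)
  kernLen <- ceiling((config@kernelRise + 12 * config@kernelDecayHalf) / resolution)

  ev <- truth@events
  if (nrow(ev) && any(ev$time_ms >= durMs))
    stop("ground-truth events extend beyond the trace duration")

  # absolute non-CF peak amplitude: 'integral' is in normalized
  # dF/F-integral units, i.e. relative to the mean spontaneous event's
  # 100 ms post-peak integral (eventAmp * K100)
  k100 <- cfKernelIntegral(params$peakT, params$peakT + 100, params)

  dff <- matrix(0, n, nt)
  for (d in seq_len(n)) {
    tr <- numeric(nt)
    evd <- ev[ev$dendrite_id == d, , drop = FALSE]
    for (i in seq_len(nrow(evd))) {
      i0 <- floor(evd$time_ms[i] / resolution) + 1
      idx <- i0:min(nt, i0 + kernLen)
      tr[idx] <- tr[idx] +
        evd$amp[i] * config@eventAmp * cfKernel(times[idx] - evd$time_ms[i], params)
    }
    ncf <- truth@noncf[truth@noncf$dendrite_id == d, , drop = FALSE]
    for (i in seq_len(nrow(ncf))) {
      rise <- ncf$rise_ms[i]
      g100 <- alphaKernelIntegral(rise, rise + 100, rise)
      hAbs <- ncf$integral[i] * config@eventAmp * k100 / g100
      i0 <- floor(ncf$onset_ms[i] / resolution) + 1
      idx <- i0:min(nt, i0 + ceiling(10 * rise / resolution))
      tr[idx] <- tr[idx] + hAbs * alphaKernel(times[idx] - ncf$onset_ms[i], rise)
    }
    dff[d, ] <- tr
  }
  if (noise && config@noiseSd > 0) {
    dff <- dff + .withSeed(seed * 211L + 31L,
                           matrix(stats::rnorm(n * nt, 0, config@noiseSd), n, nt))
  }
  F <- config@f0 * (1 + dff)
  CalciumExperiment(dff = dff, F = F, positionUm = unname(truth@roiPositions),
                    samplePeriodMs = resolution,
                    framePeriodMs = config@framePeriod,
                    protocol = protocol, truth = truth, config = config)
}

#' Bin a densely rendered experiment to frame resolution
#'
#' Averages consecutive samples so that the sample period becomes the
#' acquisition frame period (or any multiple of the current period).
#'
#' @param x a \linkS4class{CalciumExperiment}.
#' @param framePeriodMs target period, ms (default: the acquisition frame
#'   period recorded in the object).
#' @return a \linkS4class{CalciumExperiment} at frame resolution.
#' @export
binToFrames <- function(x, framePeriodMs = framePeriod(x)) {
  res <- samplePeriod(x)
  fac <- framePeriodMs / res
  if (abs(fac - round(fac)) > 1e-8)
    stop("frame period must be an integer multiple of the sample period")
  fac <- as.integer(round(fac))
  if (fac == 1L) return(x)
  nt <- (ncol(x) %/% fac) * fac
  binOne <- function(m) {
    m <- m[, seq_len(nt), drop = FALSE]
    nb <- nt %/% fac
    out <- matrix(0, nrow(m), nb)
    for (d in seq_len(nrow(m)))
      out[d, ] <- colMeans(matrix(m[d, ], fac, nb))
    out
  }
  newAssays <- lapply(as.list(assays(x)), binOne)
  md <- metadata(x)
  CalciumExperiment(dff = newAssays$dff, F = newAssays$F,
                    positionUm = rowData(x)$position_um,
                    samplePeriodMs = framePeriodMs,
                    framePeriodMs = md$frame_period_ms,
                    protocol = md$protocol, truth = md$truth,
                    config = md$config)
}

#' Simulate a complete experiment
#'
#' Convenience wrapper: protocol, ground truth and rendered traces in one
#' call.
#'
#' @inheritParams renderTraces
#' @inheritParams makeProtocol
#' @param seed optional seed overriding \code{config@seed}.
#' @return a \linkS4class{CalciumExperiment}.
#' @export
simulateExperiment <- function(config, mode = "duration",
                               lateralities = "ipsi",
                               resolution = config@renderResolution,
                               noise = TRUE, seed = NULL) {
  protocol <- makeProtocol(config, mode, lateralities, seed = seed)
  truth <- simulateEvents(config, protocol, seed = seed)
  renderTraces(truth, config, protocol, resolution = resolution,
               noise = noise, seed = seed)
}
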