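# dF/F computation and spontaneous-peak normalization.

#' Compute dF/F with a moving-percentile baseline
#'
#' The baseline Fb at each frame is the 8th percentile of the raw
#' fluorescence within a centered 1 s moving window (truncated at the trace
#' edges); dF/F = (F - Fb) / Fb.
#'
#' @param x numeric raw-fluorescence trace, or a
#'   \linkS4class{CalciumExperiment} with an \code{"F"} assay.
#' @param samplePeriodMs sample period, ms (vector method only).
#' @param windowS baseline window length, s.
#' @param percentile baseline percentile (0.08 = lowest eighth percentile).
#' @param ... passed to the vector method.
#' @return numeric dF/F trace, or a \linkS4class{CalciumExperiment} whose
#'   \code{"dff"} assay has been (re)computed from \code{"F"}.
#' @examples
#' f <- rep(100, 50); f[25] <- 120
#' computeDff(f, samplePeriodMs = 64)[25]  # 0.2
#' @export
#' @rdname computeDff
setMethod("computeDff", "numeric",
  function(x, samplePeriodMs, windowS = 1, percentile = 0.08, ...) {
    w <- max(2L, round(windowS * 1000 / samplePeriodMs))
    if (length(x) < w)
      stop("trace shorter than the baseline window")
    fb <- .rollQuantile(x, w, percentile)
    if (any(fb <= 0))
      stop("baseline fluorescence must be positive; raw F contains values <= 0")
    (x - fb) / fb
  })

#' @export
#' @rdname computeDff
setMethod("computeDff", "CalciumExperiment",
  function(x, windowS = 1, percentile = 0.08, ...) {
    Fm <- assay(x, "F")
    dff <- t(apply(Fm, 1L, computeDff, samplePeriodMs = samplePeriod(x),
                   windowS = windowS, percentile = percentile))
    assay(x, "dff", withDimnames = FALSE) <- dff
    x
  })

#' Normalize dF/F to the mean spontaneous calcium event
#'
#' Aligns the dendrite's spontaneous events on their peak sample, averages
#' them into the mean spontaneous event, and divides the whole dF/F trace
#' by that mean event's peak. After normalization the mean spontaneous
#' event has peak 1.
#'
#' @param dff numeric dF/F trace.
#' @param peakIndices integer sample indices of spontaneous event peaks.
#' @param samplePeriodMs sample period, ms.
#' @param windowMs alignment window around the peak, ms (start, end).
#' @param realignMs optionally re-center each peak on the argmax of a
#'   lightly smoothed trace within this radius (0, the default, disables:
#'   the smoothing of the asymmetric transient shifts its argmax late, so
#'   detected peak samples are used as-is).
#' @return list with \code{trace} (normalized dF/F), \code{spontPeak}
#'   (the divisor), \code{meanEvent} (the aligned mean event) and
#'   \code{peakOffset} (sample offset of the peak within meanEvent).
#' @export
normalizeToSpontaneous <- function(dff, peakIndices, samplePeriodMs,
                                   windowMs = c(-320, 640), realignMs = 0) {
  if (length(peakIndices) == 0L)
    stop("no spontaneous events: record a longer baseline before normalizing")
  pre <- floor(-windowMs[1] / samplePeriodMs)
  post <- floor(windowMs[2] / samplePeriodMs)
  n <- length(dff)
  half <- floor(realignMs / samplePeriodMs)
  if (half >= 1L) {
    w <- max(1L, round(7 / samplePeriodMs))
    if (w %% 2L == 0L) w <- w + 1L
    smv <- if (w > 1L) as.numeric(stats::filter(dff, rep(1 / w, w), sides = 2))
           else dff
    peakIndices <- vapply(peakIndices, function(p) {
      idx <- max(1L, p - half):min(n, p + half)
      v <- smv[idx]
      v[!is.finite(v)] <- -Inf
      idx[which.max(v)]
    }, integer(1))
  }
  segs <- vapply(peakIndices, function(p) {
    idx <- (p - pre):(p + post)
    out <- rep(NA_real_, pre + post + 1L)
    ok <- idx >= 1L & idx <= n
    out[ok] <- dff[idx[ok]]
    out
  }, numeric(pre + post + 1L))
  # the aligned average is left on the trace's own zero: around an event
  # the refractory keeps neighbours away, so the expected background there
  # is already near zero, and subtracting the (elevated) pre-event plateau
  # would distort the decay
  meanEvent <- rowMeans(segs, na.rm = TRUE)
  spontPeak <- max(meanEvent, na.rm = TRUE)
  if (!is.finite(spontPeak) || spontPeak <= 0)
    stop("mean spontaneous event has a non-positive peak")
  list(trace = dff / spontPeak, spontPeak = spontPeak,
       meanEvent = meanEvent / spontPeak, peakOffset = pre + 1L)
}

#' Half-decay time of a calcium event
#'
#' Time from the event peak to the first downward crossing of half the
#' peak amplitude, with linear interpolation between samples. The trace is
#' lightly smoothed first: aligning events on their detected (noisy) peak
#' sample puts a one-sample selection spike at the alignment point of the
#' average, which would otherwise inflate the reference peak.
#'
#' @param meanEvent event trace (e.g. the mean spontaneous event from
#'   [normalizeToSpontaneous()]).
#' @param peakOffset sample index of the peak within \code{meanEvent}.
#' @param samplePeriodMs sample period, ms.
#' @param smoothMs moving-average width, ms (rounded to an odd number of
#'   samples; 1 sample at coarse periods).
#' @return half-decay time in ms, or \code{NA} if the trace never falls
#'   below half the peak.
#' @export
halfDecayTime <- function(meanEvent, peakOffset, samplePeriodMs,
                          smoothMs = 5) {
  v <- as.numeric(meanEvent)
  w <- max(1L, round(smoothMs / samplePeriodMs))
  if (w %% 2L == 0L) w <- w + 1L
  if (w >= length(v)) w <- 1L
  if (w > 1L) {
    # excise the alignment sample (and immediate neighbours): being the
    # per-event argmax it carries a positive noise-selection spike that
    # would inflate the peak reference
    if (peakOffset > 2L && peakOffset + 2L <= length(v)) {
      v[peakOffset + (-1:1)] <-
        v[peakOffset - 2L] + (1:3) / 4 * (v[peakOffset + 2L] - v[peakOffset - 2L])
    }
    sm <- stats::filter(v, rep(1 / w, w), sides = 2)
    v <- ifelse(is.na(sm), v, as.numeric(sm))
    # the peak may sit next to the excised centre after smoothing
    rng <- max(1L, peakOffset - w):min(length(v), peakOffset + w)
    peakOffset <- rng[which.max(v[rng])]
  }
  target <- v[peakOffset] / 2
  j <- peakOffset
  n <- length(v)
  while (j < n && (!is.finite(v[j + 1L]) || v[j + 1L] >= target)) j <- j + 1L
  if (j >= n || !is.finite(v[j + 1L])) return(NA_real_)
  frac <- (v[j] - target) / (v[j] - v[j + 1L])
  (j - peakOffset + frac) * samplePeriodMs
}

#' Normalize every dendrite of an experiment
#'
#' Applies [normalizeToSpontaneous()] per dendrite using that dendrite's
#' detected spontaneous events, adding an \code{"ndff"} assay and a
#' \code{spont_peak} column to \code{rowData}.
#'
#' @param x a \linkS4class{CalciumExperiment} with a \code{"dff"} assay.
#' @param events classified event table (see [classifyEvents()]).
#' @return \code{x} with an \code{"ndff"} assay.
#' @export
normalizeExperiment <- function(x, events) {
  dff <- assay(x, "dff")
  ndff <- matrix(NA_real_, nrow(dff), ncol(dff))
  peaks <- rep(NA_real_, nrow(dff))
  for (d in seq_len(nrow(dff))) {
    sp <- events[events$dendrite_id == d & events$label == "spontaneous", ]
    nz <- normalizeToSpontaneous(dff[d, ], sp$peak_index, samplePeriod(x))
    ndff[d, ] <- nz$trace
    peaks[d] <- nz$spontPeak
  }
  assay(x, "ndff", withDimnames = FALSE) <- ndff
  rowData(x)$spont_peak <- peaks
  x
}
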