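# CF calcium-event detection, classification, onset latency, rates.

#' Detection template
#'
#' The CF kernel (10 ms rise, 74 ms decay half-time by default) averaged
#' over consecutive sample bins and preceded by a flat zero baseline
#' segment, used for the template-matching step of event detection. The
#' pre-onset baseline is what lets the correlation reject windows that
#' start on the decay tail of an earlier event (elevated baseline) or on a
#' slow non-CF ramp.
#'
#' @param samplePeriodMs sample period, ms.
#' @param riseMs,decayHalfMs kernel kinetics, ms.
#' @param durationMs kernel segment length, ms.
#' @param preMs baseline segment length before the kernel onset, ms.
#' @param phase sub-sample phase of the event onset within its bin, in
#'   [0, 1) (only matters when the sample period is coarse).
#' @return numeric template (unit peak before bin-averaging), with
#'   attribute \code{pre_bins} giving the number of baseline samples.
#' @export
cfTemplate <- function(samplePeriodMs, riseMs = 10, decayHalfMs = 74,
                       durationMs = 200, preMs = 50, phase = 0) {
  params <- cfKernelParams(riseMs, decayHalfMs)
  nb <- max(3L, ceiling(durationMs / samplePeriodMs))
  preBins <- max(1L, round(preMs / samplePeriodMs))
  sub <- max(1L, round(samplePeriodMs))  # ~1 ms sub-sampling for averaging
  tt <- seq(0, nb * samplePeriodMs - samplePeriodMs / sub / 2,
            by = samplePeriodMs / sub)
  k <- cfKernel(tt - phase * samplePeriodMs, params)
  structure(c(numeric(preBins), colMeans(matrix(k, sub, nb))),
            pre_bins = preBins)
}

# template bank over onset phases; a single phase suffices at (near-)dense
# sampling where bin averaging hardly distorts the kernel
.templateBank <- function(samplePeriodMs, riseMs = 10, decayHalfMs = 74) {
  phases <- if (samplePeriodMs > riseMs) c(0, 0.25, 0.5, 0.75) else 0
  lapply(phases, function(ph)
    cfTemplate(samplePeriodMs, riseMs, decayHalfMs, phase = ph))
}

# Rolling Pearson correlation of x against template (window starts).
.rollingTemplateCorr <- function(x, template) {
  L <- length(template)
  n <- length(x)
  if (L > n) stop("template longer than trace")
  dot <- stats::filter(x, rev(template), sides = 1)  # dot[i] = sum over [i-L+1, i]
  ends <- L:n
  starts <- ends - L + 1L
  dot <- as.numeric(dot)[ends]                       # indexed by window start
  cs <- cumsum(x)
  cs2 <- cumsum(x * x)
  Sx <- cs[ends] - c(0, cs)[starts]
  Sx2 <- cs2[ends] - c(0, cs2)[starts]
  St <- sum(template)
  St2 <- sum(template^2)
  num <- dot - Sx * St / L
  den <- sqrt(pmax(Sx2 - Sx^2 / L, 0) * (St2 - St^2 / L))
  r <- num / den
  r[!is.finite(r)] <- 0
  r
}

#' Detect CF calcium events
#'
#' Two-step detection: (1) the dF/F trace is cross-correlated against the
#' kernel template; local maxima of the normalized correlation at or above
#' \code{scoreThreshold} are candidate events; (2) a candidate is retained
#' only if its peak dF/F amplitude reaches \code{ampThreshold}. Candidates
#' closer together than the refractory period are merged, keeping the
#' larger-amplitude one.
#'
#' @param x numeric dF/F trace, or a \linkS4class{CalciumExperiment} with a
#'   \code{"dff"} assay (its method runs per dendrite and adds a
#'   \code{dendrite_id} column).
#' @param samplePeriodMs sample period, ms.
#' @param template detection template (default [cfTemplate()] at the trace's
#'   sample period).
#' @param ampThreshold minimum peak dF/F; default 3x the trace's noise SD,
#'   robustly estimated from the MAD of first differences.
#' @param scoreThreshold minimum template correlation.
#' @param refractoryMs deduplication window, ms.
#' @param passes detect-and-subtract iterations: after each pass the fitted
#'   kernels of accepted events are subtracted so events riding on the
#'   decay tail of a predecessor become visible to the template.
#' @param ... passed to the vector method.
#' @return data.frame with \code{peak_index}, \code{peak_time_ms}
#'   (start-of-sample convention), \code{peak_amp} and
#'   \code{template_score}.
#' @export
#' @rdname detectEvents
setMethod("detectEvents", "numeric",
  function(x, samplePeriodMs, template = NULL, ampThreshold = NULL,
           scoreThreshold = 0.8, refractoryMs = 200, passes = 2L, ...) {
    if (is.null(template)) template <- .templateBank(samplePeriodMs)
    if (is.null(ampThreshold)) ampThreshold <- 3 * .robustNoiseSd(x)
    empty <- data.frame(peak_index = integer(0), peak_time_ms = numeric(0),
                        peak_amp = numeric(0), template_score = numeric(0))
    resid <- x
    ev <- empty
    for (pass in seq_len(passes)) {
      cand <- .detectPass(resid, samplePeriodMs, template, ampThreshold,
                          scoreThreshold)
      if (nrow(ev)) {
        # one sample of slack: frame quantization can pull peaks of events
        # at exactly the refractory spacing one sample closer
        near <- vapply(cand$peak_time_ms, function(t)
          any(abs(t - ev$peak_time_ms) < refractoryMs - samplePeriodMs),
          logical(1))
        cand <- cand[!near, , drop = FALSE]
      }
      if (!nrow(cand)) break
      ev <- rbind(ev, cand)
      if (pass < passes)
        resid <- .subtractKernels(resid, cand, samplePeriodMs)
    }
    if (!nrow(ev)) return(empty)
    ev <- ev[order(ev$peak_time_ms), , drop = FALSE]
    ev <- ev[!duplicated(ev$peak_index), , drop = FALSE]
    if (nrow(ev) > 1L) {
      # enforce refractory: iterate keeping the higher-amplitude event
      repeat {
        gaps <- diff(ev$peak_time_ms)
        viol <- which(gaps < refractoryMs - samplePeriodMs)
        if (!length(viol)) break
        i <- viol[1L]
        drop <- if (ev$peak_amp[i] >= ev$peak_amp[i + 1L]) i + 1L else i
        ev <- ev[-drop, , drop = FALSE]
      }
    }
    rownames(ev) <- NULL
    ev
  })

# one template-matching + amplitude-threshold pass; `template` may be a
# single template or a bank (list) whose best score is used per window
.detectPass <- function(x, samplePeriodMs, template, ampThreshold,
                        scoreThreshold) {
  bank <- if (is.list(template)) template else list(template)
  preBins <- attr(bank[[1]], "pre_bins")
  if (is.null(preBins)) preBins <- 0L
  rs <- lapply(bank, function(tp) .rollingTemplateCorr(x, as.numeric(tp)))
  n <- min(lengths(rs))
  r <- do.call(pmax, lapply(rs, function(v) v[seq_len(n)]))
  ns <- length(r)
  isMax <- r >= scoreThreshold &
    r >= c(-Inf, r[-ns]) & r > c(r[-1], -Inf)
  cand <- which(isMax)
  if (!length(cand))
    return(data.frame(peak_index = integer(0), peak_time_ms = numeric(0),
                      peak_amp = numeric(0), template_score = numeric(0)))
  # peak search: kernel onset .. a little past the kernel rise. Kept
  # narrow: the argmax competition region conditionally suppresses
  # neighbouring noise samples in peak-aligned averages, so a wide search
  # widens that distortion.
  span <- max(1L, ceiling(40 / samplePeriodMs))
  peaks <- vapply(cand, function(s) {
    s0 <- min(length(x), s + preBins)
    idx <- s0:min(length(x), s0 + span)
    idx[which.max(x[idx])]
  }, integer(1))
  ev <- data.frame(peak_index = peaks,
                   peak_time_ms = (peaks - 1L) * samplePeriodMs,
                   peak_amp = x[peaks], template_score = r[cand])
  ev <- ev[ev$peak_amp >= ampThreshold, , drop = FALSE]
  ev[!duplicated(ev$peak_index), , drop = FALSE]
}

# subtract a fitted unit-shape kernel at every detected peak
.subtractKernels <- function(x, ev, samplePeriodMs, riseMs = 10,
                             decayHalfMs = 74) {
  shape <- cfTemplate(samplePeriodMs, riseMs, decayHalfMs,
                      durationMs = 12 * decayHalfMs, preMs = 0)
  shape <- as.numeric(shape) / max(shape)
  pk <- which.max(shape)
  for (i in seq_len(nrow(ev))) {
    s0 <- ev$peak_index[i] - pk + 1L
    idx <- seq(max(1L, s0), min(length(x), s0 + length(shape) - 1L))
    x[idx] <- x[idx] - ev$peak_amp[i] * shape[idx - s0 + 1L]
  }
  x
}

#' @export
#' @rdname detectEvents
setMethod("detectEvents", "CalciumExperiment",
  function(x, template = NULL, ampThreshold = NULL, scoreThreshold = 0.8,
           refractoryMs = 200, ...) {
    dff <- assay(x, "dff")
    sp <- samplePeriod(x)
    if (is.null(template)) template <- .templateBank(sp)
    out <- lapply(seq_len(nrow(dff)), function(d) {
      ev <- detectEvents(dff[d, ], samplePeriodMs = sp, template = template,
                         ampThreshold = ampThreshold,
                         scoreThreshold = scoreThreshold,
                         refractoryMs = refractoryMs)
      if (nrow(ev)) cbind(dendrite_id = d, ev) else NULL
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(dendrite_id = integer(0), peak_index = integer(0),
                        peak_time_ms = numeric(0), peak_amp = numeric(0),
                        template_score = numeric(0))
    out
  })

#' Classify events as spontaneous or airpuff-evoked
#'
#' An event is evoked, and linked to trial T, iff its peak falls in
#' [onset_T + 50 ms, onset_T + 200 ms) (half-open); all other events are
#' spontaneous.
#'
#' @param events detection table (with \code{peak_time_ms}).
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param windowMs evoked window relative to stimulus onset, ms.
#' @return \code{events} with added \code{label}, \code{trial_id},
#'   \code{condition}, \code{laterality} and \code{latency window} linkage.
#' @export
classifyEvents <- function(events, protocol, windowMs = EVOKED_WINDOW_MS) {
  tr <- protocol@trials
  if (nrow(tr) > 1L &&
      any(diff(tr$onset_s) * 1000 < (windowMs[2] - windowMs[1])))
    stop("invalid protocol: evoked windows of consecutive trials overlap")
  events$label <- rep("spontaneous", nrow(events))
  events$trial_id <- rep(NA_integer_, nrow(events))
  events$condition <- rep(NA_character_, nrow(events))
  events$laterality <- rep(NA_character_, nrow(events))
  if (nrow(tr) == 0L || nrow(events) == 0L) return(events)
  starts <- tr$onset_s * 1000 + windowMs[1]
  idx <- findInterval(events$peak_time_ms, starts)
  inWin <- idx >= 1L &
    events$peak_time_ms < tr$onset_s[pmax(idx, 1L)] * 1000 + windowMs[2]
  events$label[inWin] <- "evoked"
  events$trial_id[inWin] <- tr$trial_id[idx[inWin]]
  events$condition[inWin] <- tr$condition[idx[inWin]]
  events$laterality[inWin] <- tr$laterality[idx[inWin]]
  events
}

#' Estimate the onset latency of an evoked event
#'
#' The onset is the last time before the peak at which the trace crosses
#' 10% of the event's peak amplitude (measured relative to a local
#' pre-event baseline, so a slow underlying non-CF transient does not pull
#' the onset early), with linear interpolation between samples. The latency
#' is onset minus stimulus onset and must lie in (0, 200) ms.
#'
#' @param dff numeric dF/F trace of one dendrite.
#' @param samplePeriodMs sample period, ms.
#' @param peakIndex sample index of the event peak.
#' @param trialOnsetMs stimulus onset, ms.
#' @param riseMs kernel time-to-peak used to place the pre-event baseline
#'   window, ms.
#' @return onset latency in ms, or \code{NA} (event flagged) when no
#'   crossing exists before the peak or the latency falls outside
#'   (0, 200) ms.
#' @export
estimateOnsetLatency <- function(dff, samplePeriodMs, peakIndex,
                                 trialOnsetMs, riseMs = 10) {
  # local baseline: median over [peak - rise - 40, peak - rise - 5] ms
  b0 <- peakIndex - round((riseMs + 40) / samplePeriodMs)
  b1 <- peakIndex - max(1L, round((riseMs + 5) / samplePeriodMs))
  b0 <- max(1L, b0)
  base <- if (b1 >= b0) stats::median(dff[b0:b1]) else dff[max(1L, peakIndex - 1L)]
  thr <- base + 0.10 * (dff[peakIndex] - base)
  # scan backwards from the peak for the last downward crossing
  lim <- max(1L, peakIndex - ceiling(250 / samplePeriodMs))
  j <- peakIndex
  while (j > lim && dff[j] >= thr) j <- j - 1L
  if (dff[j] >= thr) return(NA_real_)  # no crossing in reach
  # linear interpolation between samples j and j+1
  tj <- (j - 1L) * samplePeriodMs
  cross <- tj + samplePeriodMs * (thr - dff[j]) / (dff[j + 1L] - dff[j])
  lat <- cross - trialOnsetMs
  if (!is.finite(lat) || lat <= 0 || lat >= 200) return(NA_real_)
  lat
}

#' Add onset latencies to a classified event table
#'
#' @param x a \linkS4class{CalciumExperiment} with a \code{"dff"} assay.
#' @param events classified event table.
#' @return \code{events} with an \code{onset_latency_ms} column (NA for
#'   spontaneous or flagged events).
#' @export
estimateLatencies <- function(x, events) {
  dff <- assay(x, "dff")
  sp <- samplePeriod(x)
  tr <- protocol(x)@trials
  onset <- stats::setNames(tr$onset_s * 1000, tr$trial_id)
  cfg <- metadata(x)$config
  rise <- if (!is.null(cfg)) cfg@kernelRise else 10
  events$onset_latency_ms <- NA_real_
  ev <- which(events$label == "evoked")
  for (i in ev) {
    events$onset_latency_ms[i] <- estimateOnsetLatency(
      dff[events$dendrite_id[i], ], sp, events$peak_index[i],
      onset[[as.character(events$trial_id[i])]], riseMs = rise)
  }
  events
}

#' Spontaneous event rate
#'
#' Spontaneous event count divided by the recording time that lies outside
#' the evoked windows, per dendrite.
#'
#' @param events classified event table.
#' @param durationS recording duration, s.
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param nDendrites number of dendrites (defaults to the largest id seen).
#' @param windowMs evoked window, ms.
#' @return data.frame with \code{dendrite_id} and \code{rate_hz}.
#' @export
spontaneousRate <- function(events, durationS, protocol,
                            nDendrites = NULL, windowMs = EVOKED_WINDOW_MS) {
  stopifnot(durationS > 0)
  if (is.null(nDendrites))
    nDendrites <- if (nrow(events)) max(events$dendrite_id) else 0L
  evokedTime <- nrow(protocol@trials) * (windowMs[2] - windowMs[1]) / 1000
  denom <- durationS - evokedTime
  counts <- vapply(seq_len(nDendrites), function(d)
    sum(events$dendrite_id == d & events$label == "spontaneous"), numeric(1))
  data.frame(dendrite_id = seq_len(nDendrites), rate_hz = counts / denom)
}

#' Match detected events against ground truth
#'
#' Greedy nearest-neighbour matching of detected peak times to true event
#' times per dendrite within a tolerance; reports recall and precision.
#'
#' @param detected detection table with \code{dendrite_id},
#'   \code{peak_time_ms}.
#' @param truth a \linkS4class{GroundTruth}.
#' @param tolMs matching tolerance, ms (default one frame at 64 ms plus the
#'   kernel rise, since true times are event onsets and detected times are
#'   peaks).
#' @param riseMs kernel time-to-peak, ms.
#' @return list with \code{recall}, \code{precision}, \code{nTrue},
#'   \code{nDetected}.
#' @export
matchEvents <- function(detected, truth, tolMs = 64, riseMs = 10) {
  tp <- 0L
  ev <- truth@events
  for (d in unique(c(detected$dendrite_id, ev$dendrite_id))) {
    # sorted two-pointer sweep; unambiguous because the refractory spacing
    # of events exceeds twice the tolerance
    tTrue <- sort(ev$time_ms[ev$dendrite_id == d] + riseMs)  # expected peaks
    tDet <- sort(detected$peak_time_ms[detected$dendrite_id == d])
    i <- 1L; j <- 1L
    while (i <= length(tTrue) && j <= length(tDet)) {
      if (abs(tDet[j] - tTrue[i]) <= tolMs) {
        tp <- tp + 1L; i <- i + 1L; j <- j + 1L
      } else if (tDet[j] < tTrue[i]) j <- j + 1L else i <- i + 1L
    }
  }
  list(recall = if (nrow(ev)) tp / nrow(ev) else NA_real_,
       precision = if (nrow(detected)) tp / nrow(detected) else NA_real_,
       nTrue = nrow(ev), nDetected = nrow(detected))
}
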