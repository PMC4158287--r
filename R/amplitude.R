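# Event-size quantification, jitter-matched spontaneous reference,
# enhancement and non-CF signal extraction.

#' dF/F-integral of a calcium event
#'
#' Trapezoidal integral of the (normalized) dF/F trace over the 100 ms
#' following the event's peak.
#'
#' @param trace numeric (normalized) dF/F trace.
#' @param samplePeriodMs sample period, ms.
#' @param peakIndex sample index of the event peak.
#' @param widthMs integration window, ms.
#' @return the integral in dF/F x ms, or \code{NA} if the window exceeds
#'   the trace (event excluded, flagged by the caller).
#' @examples
#' # rectangular pulse of height 1 covering the window -> 100 dF/F*ms
#' eventIntegral(rep(1, 200), 1, 50)
#' @export
eventIntegral <- function(trace, samplePeriodMs, peakIndex, widthMs = 100) {
  iEnd <- peakIndex + round(widthMs / samplePeriodMs)
  if (iEnd > length(trace) || peakIndex < 1L) return(NA_real_)
  idx <- peakIndex:iEnd
  .trapz((idx - 1) * samplePeriodMs, trace[idx])
}

#' Normalized event sizes
#'
#' Computes the dF/F-integral of every detected event on the normalized
#' trace and divides each by the dendrite's mean spontaneous integral, so
#' spontaneous sizes average exactly 1 per dendrite.
#'
#' @param x a \linkS4class{CalciumExperiment} with an \code{"ndff"} assay.
#' @param events classified event table.
#' @return list with \code{events} (the table with \code{integral} and
#'   \code{norm_integral} columns) and \code{spontMean} (per-dendrite mean
#'   spontaneous integral).
#' @export
eventSizes <- function(x, events) {
  ndff <- assay(x, "ndff")
  sp <- samplePeriod(x)
  events$integral <- vapply(seq_len(nrow(events)), function(i)
    eventIntegral(ndff[events$dendrite_id[i], ], sp, events$peak_index[i]),
    numeric(1))
  spontMean <- vapply(seq_len(nrow(ndff)), function(d) {
    v <- events$integral[events$dendrite_id == d &
                           events$label == "spontaneous" &
                           is.finite(events$integral)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  events$norm_integral <- events$integral / spontMean[events$dendrite_id]
  list(events = events, spontMean = spontMean)
}

#' Exclude trials with closely spaced multiple events
#'
#' Removes, per dendrite, trials in which the stimulation yielded two or
#' more events in the evoked window separated by less than \code{sepMs};
#' reports the exclusion fraction.
#'
#' @param events classified event table.
#' @param sepMs minimum separation, ms.
#' @return list with \code{keep} (logical per event row: usable for size
#'   analyses), \code{excluded} (data.frame dendrite_id/trial_id) and
#'   \code{fraction} (excluded dendrite-trials over dendrite-trials with
#'   any evoked event).
#' @export
excludeMultiEventTrials <- function(events, sepMs = 100) {
  ev <- events[events$label == "evoked", , drop = FALSE]
  keyAll <- paste(events$dendrite_id, events$trial_id)
  excluded <- NULL
  nCells <- 0L
  for (g in split(ev, paste(ev$dendrite_id, ev$trial_id))) {
    nCells <- nCells + 1L
    if (nrow(g) >= 2L && min(diff(sort(g$peak_time_ms))) < sepMs)
      excluded <- rbind(excluded,
                        data.frame(dendrite_id = g$dendrite_id[1],
                                   trial_id = g$trial_id[1]))
  }
  keep <- rep(TRUE, nrow(events))
  if (!is.null(excluded))
    keep <- !(keyAll %in% paste(excluded$dendrite_id, excluded$trial_id)) |
      events$label != "evoked"
  nExcl <- if (is.null(excluded)) 0L else nrow(excluded)
  list(keep = keep, excluded = excluded,
       fraction = if (nCells) nExcl / nCells else 0)
}

# trials x time matrix of peristimulus traces
peristimulusMatrix <- function(trace, samplePeriodMs, onsetsMs,
                               windowMs = c(-200, 800)) {
  relIdx <- seq(floor(windowMs[1] / samplePeriodMs),
                ceiling(windowMs[2] / samplePeriodMs) - 1L)
  out <- matrix(NA_real_, length(onsetsMs), length(relIdx))
  for (i in seq_along(onsetsMs)) {
    idx <- round(onsetsMs[i] / samplePeriodMs) + relIdx + 1L
    ok <- idx >= 1L & idx <= length(trace)
    out[i, ok] <- trace[idx[ok]]
  }
  attr(out, "time_ms") <- relIdx * samplePeriodMs
  out
}

#' Jitter-matched spontaneous reference trace
#'
#' Places the dendrite's mean spontaneous event at the peak time of every
#' stimulus-evoked event and averages, producing the 'sp' trace whose
#' temporal jitter matches the evoked conditions. With identical latencies
#' the reference peaks at 1; latency jitter smears and lowers the peak.
#'
#' @param meanEvent normalized mean spontaneous event (peak value 1).
#' @param peakOffset sample index of the peak within \code{meanEvent}.
#' @param eventPeakRelMs peak times of the evoked events relative to
#'   stimulus onset, ms.
#' @param samplePeriodMs sample period, ms.
#' @param windowMs peristimulus window, ms.
#' @return numeric trace on the peristimulus time base (attribute
#'   \code{time_ms}).
#' @export
buildSpReference <- function(meanEvent, peakOffset, eventPeakRelMs,
                             samplePeriodMs, windowMs = c(-200, 800)) {
  relIdx <- seq(floor(windowMs[1] / samplePeriodMs),
                ceiling(windowMs[2] / samplePeriodMs) - 1L)
  tms <- relIdx * samplePeriodMs
  acc <- numeric(length(tms))
  me <- meanEvent
  me[!is.finite(me)] <- 0
  for (tp in eventPeakRelMs) {
    src <- round((tms - tp) / samplePeriodMs) + peakOffset
    ok <- src >= 1L & src <= length(me)
    acc[ok] <- acc[ok] + me[src[ok]]
  }
  out <- acc / max(1L, length(eventPeakRelMs))
  attr(out, "time_ms") <- tms
  out
}

#' Calcium-event enhancement trace
#'
#' Pointwise difference between the evoked mean trace and the
#' jitter-matched spontaneous reference on the same time base.
#'
#' @param evokedMean,spReference traces with matching \code{time_ms}
#'   attributes.
#' @return the difference trace (attribute \code{time_ms} kept).
#' @export
enhancementTrace <- function(evokedMean, spReference) {
  stopifnot(length(evokedMean) == length(spReference))
  out <- as.numeric(evokedMean) - as.numeric(spReference)
  attr(out, "time_ms") <- attr(evokedMean, "time_ms")
  out
}

# rise time: stimulus onset to the peak of a peristimulus mean trace,
# estimated on frame-binned samples with parabolic interpolation
.riseTime <- function(trace, timeMs, framePeriodMs, searchMs = c(0, 500)) {
  sp <- timeMs[2] - timeMs[1]
  fac <- max(1L, round(framePeriodMs / sp))
  nb <- length(trace) %/% fac
  v <- colMeans(matrix(trace[seq_len(nb * fac)], fac, nb))
  ct <- colMeans(matrix(timeMs[seq_len(nb * fac)], fac, nb))  # bin centers
  ok <- which(ct >= searchMs[1] & ct <= searchMs[2])
  pk <- ok[which.max(v[ok])]
  if (pk <= 1L || pk >= nb) return(ct[pk])
  a <- v[pk - 1L]; b <- v[pk]; cc <- v[pk + 1L]
  den <- a - 2 * b + cc
  off <- if (den < 0) 0.5 * (a - cc) / den else 0
  ct[pk] + max(-1, min(1, off)) * framePeriodMs
}

#' Extract the slow non-CF calcium signal
#'
#' For each dendrite and condition, averages the normalized peristimulus
#' traces of trials without any calcium event in the evoked window
#' (baseline-subtracted using the 150 ms before stimulus onset), and
#' measures (i) the rise time from stimulus onset to the mean trace's peak
#' and (ii) per-trial dF/F-integrals over [t, t + 100 ms] with t drawn
#' uniformly in [50, 200) ms, normalized by the dendrite's mean spontaneous
#' integral.
#'
#' @param x a \linkS4class{CalciumExperiment} with an \code{"ndff"} assay.
#' @param events classified event table.
#' @param spontMean per-dendrite mean spontaneous integral (see
#'   [eventSizes()]).
#' @param seed RNG seed for the random integration windows.
#' @param windowMs peristimulus window, ms.
#' @param exclusionMs a qualifying trial must have no detected event peak
#'   in this interval around stimulus onset. The evoked window is
#'   [50, 200) ms, but the randomized integration window reaches 100 ms
#'   further and the pre-stimulus baseline 150 ms earlier; excluding
#'   events over the whole [-450, 300) span (transient tails last several
#'   decay half-times) keeps the non-CF average uncontaminated and
#'   conditions the baseline and integration windows symmetrically
#'   (otherwise the event-free selection depresses the window relative to
#'   the unconditioned baseline).
#' @return list with \code{traces} (per dendrite x condition mean traces),
#'   \code{stats} (data.frame dendrite_id, condition, n_trials, rise_ms,
#'   integral mean) and \code{missing} (dendrite/condition cells without
#'   qualifying trials).
#' @export
extractNonCF <- function(x, events, spontMean, seed = 1,
                         windowMs = c(-200, 800),
                         exclusionMs = c(-450, EVOKED_WINDOW_MS[2] + 100)) {
  ndff <- assay(x, "ndff")
  sp <- samplePeriod(x)
  tr <- protocol(x)@trials
  conds <- intersect(.allConditionLevels(), unique(tr$condition))
  stats <- list(); traces <- list(); missing <- list()
  rand <- .withSeed(seed * 503L + 19L,
                    matrix(stats::runif(nrow(ndff) * nrow(tr),
                                        EVOKED_WINDOW_MS[1],
                                        EVOKED_WINDOW_MS[2]),
                           nrow(ndff), nrow(tr)))
  onsMs <- tr$onset_s * 1000
  for (d in seq_len(nrow(ndff))) {
    pk <- events$peak_time_ms[events$dendrite_id == d]
    evTrials <- tr$trial_id[vapply(onsMs, function(o)
      any(pk >= o + exclusionMs[1] & pk < o + exclusionMs[2]), logical(1))]
    pm <- peristimulusMatrix(ndff[d, ], sp, onsMs, windowMs)
    tms <- attr(pm, "time_ms")
    preIdx <- tms >= -150 & tms < 0
    for (cc in conds) {
      rows <- which(tr$condition == cc & !(tr$trial_id %in% evTrials))
      if (!length(rows)) {
        missing[[length(missing) + 1L]] <-
          data.frame(dendrite_id = d, condition = cc)
        next
      }
      sub <- pm[rows, , drop = FALSE]
      sub <- sub - rowMeans(sub[, preIdx, drop = FALSE], na.rm = TRUE)
      mt <- colMeans(sub, na.rm = TRUE)
      rise <- .riseTime(mt, tms, framePeriod(x))
      ints <- vapply(seq_along(rows), function(k) {
        t0 <- rand[d, rows[k]]
        i0 <- which.min(abs(tms - t0))
        v <- eventIntegral(sub[k, ], sp, i0)
        v / spontMean[d]
      }, numeric(1))
      traces[[paste(d, cc, sep = "_")]] <- structure(mt, time_ms = tms)
      stats[[length(stats) + 1L]] <- data.frame(
        dendrite_id = d, condition = cc, n_trials = length(rows),
        rise_ms = rise, integral = mean(ints, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  list(traces = traces,
       stats = if (length(stats)) do.call(rbind, stats) else data.frame(),
       missing = if (length(missing)) do.call(rbind, missing) else NULL)
}

#' Compare calcium-event enhancement with the non-CF signal
#'
#' Per condition, the paired across-dendrite mean and SEM of the
#' enhancement integral and the non-CF integral, their difference, and a
#' supralinearity flag raised when the paired difference exceeds its
#' one-sided t critical value at level \code{conf} (~2 SEM for many
#' dendrites).
#'
#' @param enh data.frame dendrite_id, condition, integral (enhancement).
#' @param ncf data.frame dendrite_id, condition, integral (non-CF).
#' @param conf one-sided confidence level of the supralinearity flag.
#' @return data.frame per condition with means, SEMs, difference and
#'   \code{supralinear} flag.
#' @export
linearityComparison <- function(enh, ncf, conf = 0.975) {
  m <- merge(enh, ncf, by = c("dendrite_id", "condition"),
             suffixes = c("_enh", "_ncf"))
  out <- do.call(rbind, lapply(split(m, m$condition), function(g) {
    dd <- g$integral_enh - g$integral_ncf
    sem <- function(v) stats::sd(v) / sqrt(length(v))
    crit <- if (nrow(g) > 1L) stats::qt(conf, nrow(g) - 1L) else Inf
    data.frame(condition = g$condition[1], n = nrow(g),
               enhancement_mean = mean(g$integral_enh),
               enhancement_sem = sem(g$integral_enh),
               noncf_mean = mean(g$integral_ncf),
               noncf_sem = sem(g$integral_ncf),
               diff_mean = mean(dd), diff_sem = sem(dd),
               supralinear = mean(dd) > crit * sem(dd),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[match(intersect(.allConditionLevels(), out$condition), out$condition), ,
      drop = FALSE]
}
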