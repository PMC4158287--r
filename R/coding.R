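# Per-dendrite probability coding, latency statistics, categorization,
# laterality.

#' Calcium-event probability per condition
#'
#' Per dendrite and condition, the fraction of trials with at least one
#' evoked event. The spontaneous reference 'sp' is the fraction of matched
#' 150 ms pre-stimulus windows (one per trial) containing any event peak.
#'
#' @param events classified event table.
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param nDendrites number of dendrites covered by \code{events}.
#' @param spWindowMs length of the pre-stimulus spontaneous window, ms.
#' @param laterality restrict to trials of one side (default: all).
#' @return data.frame with \code{dendrite_id}, \code{condition} (including
#'   "sp") and \code{prob}.
#' @export
eventProbability <- function(events, protocol, nDendrites = NULL,
                             spWindowMs = 150, laterality = NULL) {
  tr <- protocol@trials
  if (!is.null(laterality)) tr <- tr[tr$laterality == laterality, , drop = FALSE]
  stopifnot(nrow(tr) > 0L)
  if (is.null(nDendrites))
    nDendrites <- if (nrow(events)) max(events$dendrite_id) else 0L
  conds <- intersect(.allConditionLevels(), unique(tr$condition))
  out <- list()
  for (d in seq_len(nDendrites)) {
    evd <- events[events$dendrite_id == d, , drop = FALSE]
    probs <- vapply(conds, function(cc) {
      tid <- tr$trial_id[tr$condition == cc]
      hit <- unique(evd$trial_id[evd$label == "evoked"])
      sum(tid %in% hit) / length(tid)
    }, numeric(1))
    # spontaneous chance in matched pre-stimulus windows
    pre <- vapply(tr$onset_s * 1000, function(o)
      any(evd$peak_time_ms >= o - spWindowMs & evd$peak_time_ms < o),
      logical(1))
    out[[d]] <- data.frame(dendrite_id = d,
                           condition = c(conds, "sp"),
                           prob = c(probs, mean(pre)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# wide dendrite x condition matrix from the long probability table
probabilityMatrix <- function(probTable) {
  conds <- intersect(c(.allConditionLevels(), "sp"), unique(probTable$condition))
  ids <- sort(unique(probTable$dendrite_id))
  m <- matrix(NA_real_, length(ids), length(conds),
              dimnames = list(paste0("den", ids), conds))
  for (i in seq_len(nrow(probTable)))
    m[match(probTable$dendrite_id[i], ids),
      probTable$condition[i]] <- probTable$prob[i]
  m
}

#' Categorize a dendrite's duration-response profile
#'
#' Category 1: graded — probability shares the rank order of the stimulus
#' durations (all conditions responsive above the spontaneous-corrected
#' floor, positive trend, and a straight-line fit no worse than the best
#' step fit). Categories 2-5: threshold-like — the profile is best fit by a
#' step at duration k (category 1 + k), found by least squares over the
#' possible step positions. Dendrites with no condition above the floor get
#' the highest threshold category and an unresponsive flag.
#'
#' @param probs named probability vector in increasing-duration order.
#' @param sp spontaneous-window probability.
#' @param nTrials trials per condition (sets the binomial tolerance).
#' @return list with \code{category} (integer), \code{threshold} (condition
#'   index or NA for graded) and \code{unresponsive} flag.
#' @export
categorizeDendrite <- function(probs, sp = 0, nTrials = 35) {
  k <- length(probs)
  stopifnot(k >= 2L)
  se <- sqrt(pmax(probs * (1 - probs), 0.25 / nTrials) / nTrials)
  floorP <- sp + sqrt(max(sp * (1 - sp), 0.25 / nTrials) / nTrials)

  # best step fit over the k possible threshold positions
  stepSse <- vapply(seq_len(k), function(thr) {
    lowIdx <- seq_len(k) < thr
    lo <- if (any(lowIdx)) mean(probs[lowIdx]) else NULL
    hi <- mean(probs[!lowIdx])
    sum((probs - ifelse(lowIdx, if (is.null(lo)) 0 else lo, hi))^2)
  }, numeric(1))
  bestThr <- which.min(stepSse)

  if (all(probs <= floorP))
    return(list(category = 1L + k, threshold = k, unresponsive = TRUE))

  # graded test: every condition responsive, rank order preserved within
  # one binomial SE, positive overall trend, and a line fits at least as
  # well as the best step
  x <- seq_len(k)
  fit <- stats::lm.fit(cbind(1, x), probs)
  linSse <- sum(fit$residuals^2)
  rankOk <- all(diff(probs) > -(se[-k] + se[-1]) / 2) &&
    probs[k] - probs[1] > (se[1] + se[k]) / 2
  graded <- all(probs > floorP) && rankOk && fit$coefficients[2] > 0 &&
    linSse <= stepSse[bestThr]
  if (graded)
    return(list(category = 1L, threshold = NA_integer_, unresponsive = FALSE))
  list(category = 1L + bestThr, threshold = bestThr, unresponsive = FALSE)
}

#' Onset-latency statistics per dendrite and condition
#'
#' Median latency and median absolute deviation (MAD) from it, per dendrite
#' and condition; the experiment summary is the mean with SEM across
#' dendrites that contribute at least \code{minEvents} latencies.
#'
#' @param events classified event table with \code{onset_latency_ms}.
#' @param minEvents minimum latencies per dendrite/condition cell to enter
#'   the summary.
#' @return list with \code{perDendrite} and \code{summary} data.frames.
#' @export
latencyStats <- function(events, minEvents = 10L) {
  ev <- events[events$label == "evoked" & is.finite(events$onset_latency_ms), ,
               drop = FALSE]
  if (!nrow(ev))
    return(list(perDendrite = data.frame(), summary = data.frame()))
  per <- do.call(rbind, lapply(
    split(ev, list(ev$dendrite_id, ev$condition), drop = TRUE),
    function(g) data.frame(dendrite_id = g$dendrite_id[1],
                           condition = g$condition[1], n = nrow(g),
                           median_ms = stats::median(g$onset_latency_ms),
                           mad_ms = jitterMad(g$onset_latency_ms),
                           stringsAsFactors = FALSE)))
  rownames(per) <- NULL
  keep <- per[per$n >= minEvents, , drop = FALSE]
  summ <- do.call(rbind, lapply(split(keep, keep$condition), function(g)
    data.frame(condition = g$condition[1], n_dendrites = nrow(g),
               median_mean = mean(g$median_ms),
               median_sem = stats::sd(g$median_ms) / sqrt(nrow(g)),
               mad_mean = mean(g$mad_ms),
               mad_sem = stats::sd(g$mad_ms) / sqrt(nrow(g)),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(perDendrite = per, summary = summ)
}

#' Event counts per latency interval
#'
#' Counts evoked events per dendrite, condition and latency window
#' (default [0, 75) and [75, 150) ms, half-open).
#'
#' @param events classified event table with \code{onset_latency_ms}.
#' @param windows list of c(lo, hi) latency intervals, ms.
#' @return data.frame with \code{dendrite_id}, \code{condition},
#'   \code{window}, \code{count}.
#' @export
latencyWindowCounts <- function(events,
                                windows = list(c(0, 75), c(75, 150))) {
  ev <- events[events$label == "evoked" & is.finite(events$onset_latency_ms), ,
               drop = FALSE]
  grid <- expand.grid(dendrite_id = sort(unique(ev$dendrite_id)),
                      condition = sort(unique(ev$condition)),
                      window = vapply(windows, function(w)
                        sprintf("[%g,%g)", w[1], w[2]), character(1)),
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(d, cc, wl) {
    w <- windows[[match(wl, vapply(windows, function(w)
      sprintf("[%g,%g)", w[1], w[2]), character(1)))]]
    sum(ev$dendrite_id == d & ev$condition == cc &
          ev$onset_latency_ms >= w[1] & ev$onset_latency_ms < w[2])
  }, grid$dendrite_id, grid$condition, grid$window)
  grid
}

#' Classify the laterality of a dendrite's CF receptive field
#'
#' A dendrite is responsive to a side if its strongest-condition evoked
#' probability on that side exceeds the spontaneous chance level (one-sided
#' binomial test, Bonferroni-corrected over dendrites). Dendrites
#' responsive to both sides are bilateral, to the ipsilateral side only are
#' ipsi-specific, to neither are unresponsive.
#'
#' @param events classified event table.
#' @param protocol a \linkS4class{StimulusProtocol} containing both
#'   lateralities.
#' @param nDendrites dendrites covered by \code{events}.
#' @param alpha significance level before Bonferroni correction.
#' @return data.frame with \code{dendrite_id} and \code{laterality}
#'   (\code{ipsi_specific}, \code{bilateral}, \code{unresponsive}, or
#'   \code{contra_specific}).
#' @export
classifyLaterality <- function(events, protocol, nDendrites = NULL,
                               alpha = 0.05) {
  tr <- protocol@trials
  if (!all(c("ipsi", "contra") %in% tr$laterality))
    stop("laterality undefined: protocol lacks ipsi or contra trials")
  if (is.null(nDendrites))
    nDendrites <- if (nrow(events)) max(events$dendrite_id) else 0L
  alphaAdj <- alpha / max(1L, nDendrites)
  probs <- eventProbability(events, protocol, nDendrites)
  out <- data.frame(dendrite_id = seq_len(nDendrites),
                    laterality = NA_character_)
  for (d in seq_len(nDendrites)) {
    pd <- probs[probs$dendrite_id == d, ]
    sp <- max(pd$prob[pd$condition == "sp"], 1 / (2 * nrow(tr)))
    responsive <- vapply(c("ipsi", "contra"), function(side) {
      ts <- tr[tr$laterality == side, , drop = FALSE]
      conds <- unique(ts$condition)
      hit <- unique(events$trial_id[events$dendrite_id == d &
                                      events$label == "evoked"])
      ks <- vapply(conds, function(cc) {
        tid <- ts$trial_id[ts$condition == cc]
        sum(tid %in% hit)
      }, numeric(1))
      ns <- vapply(conds, function(cc) sum(ts$condition == cc), numeric(1))
      best <- which.max(ks / ns)
      stats::binom.test(ks[best], ns[best], p = min(sp, 0.999),
                        alternative = "greater")$p.value <= alphaAdj
    }, logical(1))
    out$laterality[d] <- if (responsive["ipsi"] && responsive["contra"])
      "bilateral"
    else if (responsive["ipsi"]) "ipsi_specific"
    else if (responsive["contra"]) "contra_specific"
    else "unresponsive"
  }
  out
}
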