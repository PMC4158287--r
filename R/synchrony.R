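# Population coactivation, joint probabilities, extra synchrony,
# distance-dependent spontaneous correlation.

#' Identify responsive dendrites
#'
#' A dendrite is responsive if its evoked probability for the strongest
#' condition exceeds the spontaneous-window chance level (one-sided
#' binomial test).
#'
#' @param events classified event table.
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param nDendrites dendrites covered by \code{events}.
#' @param alpha significance level.
#' @return integer vector of responsive dendrite ids.
#' @export
responsiveDendrites <- function(events, protocol, nDendrites = NULL,
                                alpha = 0.05) {
  tr <- protocol@trials
  if (is.null(nDendrites))
    nDendrites <- if (nrow(events)) max(events$dendrite_id) else 0L
  probs <- eventProbability(events, protocol, nDendrites)
  keep <- integer(0)
  for (d in seq_len(nDendrites)) {
    pd <- probs[probs$dendrite_id == d, ]
    sp <- max(pd$prob[pd$condition == "sp"], 1 / (2 * nrow(tr)))
    conds <- pd$condition[pd$condition != "sp"]
    hit <- unique(events$trial_id[events$dendrite_id == d &
                                    events$label == "evoked"])
    ks <- vapply(conds, function(cc) {
      tid <- tr$trial_id[tr$condition == cc]
      sum(tid %in% hit)
    }, numeric(1))
    ns <- vapply(conds, function(cc) sum(tr$condition == cc), numeric(1))
    best <- which.max(ks / ns)
    p <- stats::binom.test(ks[best], ns[best], p = min(sp, 0.999),
                           alternative = "greater")$p.value
    if (p <= alpha) keep <- c(keep, d)
  }
  keep
}

#' Per-trial population coactivation
#'
#' Fraction of responsive dendrites with an airpuff-evoked calcium event on
#' each trial (the evoked window spans 150 ms), plus per-condition means.
#' Fields of view with fewer than \code{minResponsive} responsive dendrites
#' are excluded, mirroring the inclusion rule of simultaneous population
#' imaging.
#'
#' @param events classified event table.
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param responsive integer ids of responsive dendrites (default:
#'   [responsiveDendrites()]).
#' @param minResponsive minimum simultaneously imaged responsive dendrites.
#' @return list with \code{perTrial} (trial_id, condition, fraction) and
#'   \code{perCondition} (condition, mean, sem) data.frames.
#' @export
coactivationFraction <- function(events, protocol, responsive = NULL,
                                 minResponsive = 6L) {
  tr <- protocol@trials
  if (is.null(responsive)) responsive <- responsiveDendrites(events, protocol)
  if (length(responsive) < minResponsive)
    stop("experiment excluded: only ", length(responsive),
         " responsive dendrites (need at least ", minResponsive, ")",
         call. = FALSE)
  ev <- events[events$label == "evoked" &
                 events$dendrite_id %in% responsive, , drop = FALSE]
  frac <- vapply(tr$trial_id, function(tid)
    length(unique(ev$dendrite_id[ev$trial_id == tid])) / length(responsive),
    numeric(1))
  perTrial <- data.frame(trial_id = tr$trial_id, condition = tr$condition,
                         fraction = frac, stringsAsFactors = FALSE)
  perCondition <- do.call(rbind, lapply(split(perTrial, perTrial$condition),
    function(g) data.frame(condition = g$condition[1],
                           mean = mean(g$fraction),
                           sem = stats::sd(g$fraction) / sqrt(nrow(g)),
                           stringsAsFactors = FALSE)))
  rownames(perCondition) <- NULL
  list(perTrial = perTrial, perCondition = perCondition,
       responsive = responsive)
}

#' Measured and independent joint probabilities for dendrite pairs
#'
#' Per condition and pair: the measured joint probability is the fraction
#' of trials in which both dendrites had an evoked event; the independent
#' joint probability is the product of the two marginal probabilities
#' (P_ij = P_i P_j). The spontaneous condition 'sp' uses the matched
#' 150 ms pre-stimulus windows.
#'
#' @param events classified event table.
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param dendrites dendrite ids to pair (e.g. the responsive set).
#' @param spWindowMs pre-stimulus window length, ms.
#' @return data.frame with \code{i}, \code{j}, \code{condition},
#'   \code{measured}, \code{independent}.
#' @export
pairJointProbability <- function(events, protocol, dendrites,
                                 spWindowMs = 150) {
  stopifnot(length(dendrites) >= 2L)
  tr <- protocol@trials
  conds <- intersect(.allConditionLevels(), unique(tr$condition))
  # trial x dendrite indicator of evoked response
  hitMat <- matrix(vapply(dendrites, function(d) {
    hit <- unique(events$trial_id[events$dendrite_id == d &
                                    events$label == "evoked"])
    tr$trial_id %in% hit
  }, logical(nrow(tr))), nrow = nrow(tr))
  # pre-stimulus indicator for 'sp'
  preMat <- matrix(vapply(dendrites, function(d) {
    pk <- events$peak_time_ms[events$dendrite_id == d]
    vapply(tr$onset_s * 1000, function(o)
      any(pk >= o - spWindowMs & pk < o), logical(1))
  }, logical(nrow(tr))), nrow = nrow(tr))
  pairs <- utils::combn(seq_along(dendrites), 2L)
  out <- list()
  for (cc in c(conds, "sp")) {
    rows <- if (cc == "sp") rep(TRUE, nrow(tr)) else tr$condition == cc
    M <- if (cc == "sp") preMat else hitMat
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1, p]; b <- pairs[2, p]
      xi <- M[rows, a]; xj <- M[rows, b]
      out[[length(out) + 1L]] <- data.frame(
        i = dendrites[a], j = dendrites[b], condition = cc,
        measured = mean(xi & xj), independent = mean(xi) * mean(xj),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extra synchrony
#'
#' 100 x (measured - independent joint probability), averaged across
#' dendrite pairs, per condition.
#'
#' @param pairStats output of [pairJointProbability()].
#' @return data.frame with \code{condition}, \code{mean_pct},
#'   \code{sem_pct}, \code{n_pairs}.
#' @export
extraSynchrony <- function(pairStats) {
  xs <- 100 * (pairStats$measured - pairStats$independent)
  out <- do.call(rbind, lapply(split(seq_len(nrow(pairStats)),
                                     pairStats$condition), function(ii)
    data.frame(condition = pairStats$condition[ii[1]],
               mean_pct = mean(xs[ii]),
               sem_pct = stats::sd(xs[ii]) / sqrt(length(ii)),
               n_pairs = length(ii), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[match(intersect(c(.allConditionLevels(), "sp"), out$condition),
            out$condition), , drop = FALSE]
}

#' Distance dependence of spontaneous co-activation
#'
#' Binarizes each dendrite's spontaneous event peaks per frame (outside the
#' evoked windows), computes the Pearson correlation per dendrite pair as a
#' function of mediolateral separation, and compares with a shuffled-frame
#' control in which each dendrite's frame order is permuted independently.
#'
#' @param events classified event table.
#' @param positionsUm mediolateral ROI position per dendrite, um.
#' @param durationS recording duration, s.
#' @param framePeriodMs frame period for binarization, ms.
#' @param protocol optional protocol; evoked-window frames are dropped.
#' @param nShuffles shuffle repetitions for the control.
#' @param binUm distance bin width, um.
#' @param seed RNG seed for the shuffles.
#' @return list with \code{pairs} (distance, r, r_shuffled per pair) and
#'   \code{byDistance} (binned means).
#' @export
spontDistanceCorrelation <- function(events, positionsUm, durationS,
                                     framePeriodMs = 64, protocol = NULL,
                                     nShuffles = 100, binUm = 50, seed = 1) {
  n <- length(positionsUm)
  stopifnot(n >= 2L)
  nf <- floor(durationS * 1000 / framePeriodMs)
  frameOk <- rep(TRUE, nf)
  if (!is.null(protocol) && nrow(protocol@trials)) {
    tms <- (seq_len(nf) - 1L) * framePeriodMs
    for (o in protocol@trials$onset_s * 1000)
      frameOk <- frameOk & !(tms >= o + EVOKED_WINDOW_MS[1] &
                               tms < o + EVOKED_WINDOW_MS[2])
  }
  rast <- sapply(seq_len(n), function(d) {
    sp <- events[events$dendrite_id == d & events$label == "spontaneous", ]
    v <- logical(nf)
    fi <- floor(sp$peak_time_ms / framePeriodMs) + 1L
    v[fi[fi >= 1L & fi <= nf]] <- TRUE
    v[frameOk]
  })
  pairs <- utils::combn(n, 2L)
  res <- .withSeed(seed * 401L + 7L, {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
      a <- pairs[1, p]; b <- pairs[2, p]
      xa <- rast[, a]; xb <- rast[, b]
      if (stats::sd(xa) == 0 || stats::sd(xb) == 0) return(NULL)
      rsh <- mean(vapply(seq_len(nShuffles), function(s)
        stats::cor(xa[sample.int(length(xa))], xb[sample.int(length(xb))]),
        numeric(1)))
      data.frame(i = a, j = b,
                 distance_um = abs(positionsUm[a] - positionsUm[b]),
                 r = stats::cor(xa, xb), r_shuffled = rsh)
    }))
  })
  if (is.null(res)) stop("no dendrite pair with variance in both rasters")
  bins <- floor(res$distance_um / binUm)
  byDist <- do.call(rbind, lapply(split(res, bins), function(g)
    data.frame(distance_um = (floor(g$distance_um[1] / binUm) + 0.5) * binUm,
               r_mean = mean(g$r), r_shuffled_mean = mean(g$r_shuffled),
               n_pairs = nrow(g))))
  rownames(byDist) <- NULL
  list(pairs = res, byDistance = byDist[order(byDist$distance_um), ])
}
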