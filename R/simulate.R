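# Ground-truth event simulation.
#
# Spontaneous CF events are homogeneous Poisson per dendrite with a
# refractory period; a distance-dependent fraction of them is shared
# between dendrites (primary events are copied to neighbours with
# probability spontShare * exp(-d/spontSyncScale), and primary rates are
# rescaled so every dendrite keeps the configured marginal rate).
#
# Evoked events: per trial, a shared facilitation state S ~
# Bernoulli(sharedDriveProb[condition]) is drawn once for the field of
# view. Each dendrite fires with an elevated probability when S = 1 and a
# depressed one when S = 0, calibrated so the marginal equals its true
# profile value; this yields extra synchrony with a closed-form value
# q(1-q)(pHi - pLo)^2 per pair. Onset latencies come from the calibrated
# scaled-Beta distribution of the condition; at most one evoked event per
# trial per dendrite.
#
# Spontaneous events whose transient peak would fall inside a trial's
# evoked classification window are suppressed: the stimulated olivary
# volley dominates that window, and this keeps the marginal evoked
# frequency exactly equal to the configured profile. Time outside evoked
# windows is unaffected, which is also the time base the spontaneous-rate
# estimator uses.

# Boost/depression pair with marginal p under shared-state probability q.
.sharedRates <- function(p, q, boost = 1.5) {
  if (q <= 0) return(c(hi = p, lo = p))
  if (q >= 1) return(c(hi = p, lo = p))
  hi <- min(1, boost * p, p / q)
  lo <- (p - q * hi) / (1 - q)
  c(hi = hi, lo = lo)
}

# Latency support on event onsets: peaks must land in EVOKED_WINDOW_MS.
.latencySupport <- function(config) {
  EVOKED_WINDOW_MS - config@kernelRise
}

# cache of calibrated latency fits (pure function of its key)
.latencyCache <- new.env(parent = emptyenv())

# expected per-dendrite sample median/MAD of detected-latency estimates
# under a mixture of response probabilities, at nTrials trials; mirrors the
# analysis convention of at least `minEvents` latencies per dendrite
.latencyEstimatorStats <- function(fit, pmix, wmix, nTrials, R = 3000,
                                   minEvents = 10L, nDendrites = 97L) {
  .withSeed(902401L, {
    meds <- numeric(0); mads <- numeric(0)
    for (k in seq_along(pmix)) {
      nrep <- round(R * wmix[k])
      if (nrep < 1L) next
      ns <- stats::rbinom(nrep, nTrials, pmix[k])
      ns <- ns[ns >= minEvents]
      if (!length(ns)) next
      st <- vapply(ns, function(n) {
        x <- rLatency(n, fit)
        m <- stats::median(x)
        c(m, stats::median(abs(x - m)))
      }, numeric(2))
      meds <- c(meds, st[1, ]); mads <- c(mads, st[2, ])
    }
    if (!length(meds))
      c(med = NA_real_, mad = NA_real_, med_sem = NA_real_, mad_sem = NA_real_)
    else
      c(med = mean(meds), mad = mean(mads),
        med_sem = stats::sd(meds) / sqrt(nDendrites),
        mad_sem = stats::sd(mads) / sqrt(nDendrites))
  })
}

# Latency distribution for one condition. With estimator-centred
# calibration the population targets are adjusted (damped fixed point,
# projected onto the family's feasibility frontier MAD < median - lo) so
# that the expectation of the per-dendrite median/MAD estimator at the
# study's trial counts equals the configured values.
.conditionLatencyFit <- function(config, cc, condsOrdered) {
  m0 <- config@latencyMedian[[cc]]
  d0 <- config@latencyMad[[cc]]
  supp <- .latencySupport(config)
  popFit <- function() solveLatencyDist(m0, d0, supp[1], supp[2])
  if (config@latencyCalibration == "population" ||
      config@trialsPerCondition < 10L)
    return(popFit())
  nc <- length(condsOrdered)
  i <- match(cc, condsOrdered)
  g <- config@gradedFraction
  pmix <- c(config@evokedProb[[cc]], config@evokedProb[[condsOrdered[nc]]],
            0.05)
  wmix <- c(g, (1 - g) * i / nc, (1 - g) * (1 - i / nc))
  key <- paste(signif(c(m0, d0, supp, config@trialsPerCondition, pmix, wmix),
                      8), collapse = "_")
  if (!is.null(.latencyCache[[key]])) return(.latencyCache[[key]])
  nT <- config@trialsPerCondition
  # worst residual of the estimator expectation, in across-dendrite SEMs
  score <- function(fit) {
    est <- .latencyEstimatorStats(fit, pmix, wmix, nT)
    if (!is.finite(est[["med"]])) return(list(z = Inf, est = est))
    list(z = max(abs(est[["med"]] - m0) / est[["med_sem"]],
                 abs(est[["mad"]] - d0) / est[["mad_sem"]]), est = est)
  }
  tryFit <- function(tm, td) tryCatch(
    solveLatencyDist(tm, td, supp[1], supp[2]), error = function(e) NULL)

  tm <- m0; td <- d0
  fit <- popFit()
  best <- list(fit = fit, z = score(fit)$z)
  bound <- FALSE
  for (it in 1:8) {
    est <- .latencyEstimatorStats(fit, pmix, wmix, nT)
    if (!is.finite(est[["med"]])) break
    tm <- tm - 0.6 * (est[["med"]] - m0)
    td <- td - 0.6 * (est[["mad"]] - d0)
    if (td > tm - supp[1] - 0.3) {        # family frontier: MAD < median - lo
      td <- tm - supp[1] - 0.3
      bound <- TRUE
    }
    td <- max(1, td)
    fit2 <- tryFit(tm, td)
    if (is.null(fit2)) break
    fit <- fit2
    z <- score(fit)$z
    if (z < best$z) best <- list(fit = fit, z = z)
  }
  if (bound && best$z > 0.5) {
    # the unconstrained optimum is infeasible: balance the two residuals
    # along the frontier instead
    for (tm2 in m0 - seq(0.5, 5, by = 0.75)) {
      fit2 <- tryFit(tm2, tm2 - supp[1] - 0.3)
      if (is.null(fit2)) next
      z <- score(fit2)$z
      if (z < best$z) best <- list(fit = fit2, z = z)
    }
  }
  .latencyCache[[key]] <- best$fit
  best$fit
}

#' Simulate ground-truth CF activity for one experiment
#'
#' Draws spontaneous and evoked calcium events plus per-trial non-CF
#' components for \code{config@nDendrites} dendrites under the given
#' stimulus protocol. Deterministic given \code{config@seed}.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param protocol a \linkS4class{StimulusProtocol} (may be empty for a
#'   purely spontaneous recording of \code{config@spontDuration} seconds).
#' @param seed optional seed overriding \code{config@seed} (used by the
#'   pipeline to decorrelate experiments).
#' @return a \linkS4class{GroundTruth}.
#' @export
simulateEvents <- function(config, protocol, seed = NULL) {
  stopifnot(is(config, "GeneratorConfig"), is(protocol, "StimulusProtocol"))
  if (is.null(seed)) seed <- config@seed
  .withSeed(seed * 101L + 17L, .simulateEventsImpl(config, protocol))
}

.simulateEventsImpl <- function(config, protocol) {
  n <- config@nDendrites
  positions <- stats::setNames(config@dendriteSpacing * (seq_len(n) - 1),
                               paste0("den", seq_len(n)))
  trials <- protocol@trials
  durS <- .recordingDuration(protocol, config)
  durMs <- durS * 1000
  supp <- .latencySupport(config)

  conds <- unique(trials$condition)
  condsOrdered <- intersect(.allConditionLevels(), conds)

  # per-dendrite response profiles -----------------------------------------
  type <- ifelse(stats::runif(n) < config@gradedFraction, "graded", "threshold")
  latType <- ifelse(stats::runif(n) < config@bilateralFraction, "bilateral", "ipsi")
  nc <- length(condsOrdered)
  profiles <- matrix(0, n, max(nc, 1L),
                     dimnames = list(names(positions),
                                     if (nc) condsOrdered else "none"))
  if (nc) {
    for (d in seq_len(n)) {
      if (type[d] == "graded") {
        profiles[d, ] <- config@evokedProb[condsOrdered]
      } else {
        k <- sample.int(nc, 1L)
        hi <- config@evokedProb[condsOrdered[nc]]
        profiles[d, ] <- ifelse(seq_len(nc) >= k, hi, 0.05)
      }
    }
  }

  # latency distributions per condition ------------------------------------
  latFits <- lapply(stats::setNames(condsOrdered, condsOrdered), function(cc)
    .conditionLatencyFit(config, cc, condsOrdered))

  # spontaneous events ------------------------------------------------------
  shareMat <- matrix(0, n, n)
  if (n > 1L && config@spontSyncScale > 0 && config@spontShare > 0) {
    dmat <- abs(outer(positions, positions, "-"))
    shareMat <- config@spontShare * exp(-dmat / config@spontSyncScale)
    diag(shareMat) <- 0
  }
  # primary rates alpha solve r*(alpha + S^T alpha) = r so marginals stay put
  alpha <- tryCatch(solve(diag(n) + t(shareMat), rep(1, n)),
                    error = function(e) rep(1, n))
  alpha <- pmin(pmax(alpha, 0), 1)

  # refractory thinning acts as a non-paralyzable dead time: kept events
  # form a renewal process of rate lambda/(1 + lambda*tau). Draw at the
  # inverted rate so the realized spontaneous rate equals spontRate.
  tauS <- config@refractory / 1000
  if (config@spontRate * tauS >= 1)
    stop("spontRate and refractory are incompatible (dead-time saturation)")
  effRate <- config@spontRate / (1 - config@spontRate * tauS)

  spont <- vector("list", n)
  for (d in seq_len(n)) {
    nEv <- stats::rpois(1L, effRate * alpha[d] * durS)
    tEv <- sort(stats::runif(nEv, 0, durMs))
    spont[[d]] <- c(spont[[d]], tEv)
    if (nEv && n > 1L) {
      for (j in seq_len(n)[-d]) {
        take <- stats::runif(nEv) < shareMat[d, j]
        if (any(take)) spont[[j]] <- c(spont[[j]], tEv[take])
      }
    }
  }
  spontDf <- do.call(rbind, lapply(seq_len(n), function(d) {
    if (length(spont[[d]]) == 0L) return(NULL)
    data.frame(dendrite_id = d, time_ms = sort(spont[[d]]),
               amp = exp(stats::rnorm(length(spont[[d]]),
                                      -config@ampJitterSd^2 / 2,
                                      config@ampJitterSd)),
               origin = "spontaneous", trial_id = NA_integer_,
               condition = NA_character_, latency_ms = NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(spontDf))
    spontDf <- data.frame(dendrite_id = integer(0), time_ms = numeric(0),
                          amp = numeric(0), origin = character(0),
                          trial_id = integer(0), condition = character(0),
                          latency_ms = numeric(0), stringsAsFactors = FALSE)

  # suppress spontaneous events whose onsets fall in an evoked window
  if (nrow(trials) && nrow(spontDf)) {
    onsMs <- trials$onset_s * 1000
    bad <- rep(FALSE, nrow(spontDf))
    for (o in onsMs)
      bad <- bad | (spontDf$time_ms >= o + supp[1] & spontDf$time_ms < o + supp[2])
    spontDf <- spontDf[!bad, , drop = FALSE]
  }

  # evoked events and shared state ------------------------------------------
  sharedState <- data.frame(trial_id = trials$trial_id,
                            shared = rep(FALSE, nrow(trials)))
  evokedList <- vector("list", nrow(trials))
  noncfList <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    cc <- trials$condition[i]
    q <- config@sharedDriveProb[[cc]]
    shared <- stats::runif(1) < q
    sharedState$shared[i] <- shared
    onsetMs <- trials$onset_s[i] * 1000
    contra <- trials$laterality[i] == "contra"
    pMarg <- profiles[, cc]
    if (contra) pMarg <- ifelse(latType == "bilateral", pMarg, 0)
    fireP <- vapply(pMarg, function(p) {
      r <- .sharedRates(p, q)
      unname(if (shared) r["hi"] else r["lo"])
    }, numeric(1))
    fired <- which(stats::runif(n) < fireP)
    if (length(fired)) {
      lat <- rLatency(length(fired), latFits[[cc]])
      evokedList[[i]] <- data.frame(
        dendrite_id = fired, time_ms = onsetMs + lat,
        amp = config@eventGain[[cc]] *
          exp(stats::rnorm(length(fired), -config@ampJitterSd^2 / 2,
                           config@ampJitterSd)),
        origin = "evoked", trial_id = trials$trial_id[i],
        condition = cc, latency_ms = lat, stringsAsFactors = FALSE)
    }
    noncfList[[i]] <- data.frame(
      trial_id = trials$trial_id[i], dendrite_id = seq_len(n),
      condition = cc, onset_ms = onsetMs,
      rise_ms = config@noncfRise[[cc]],
      integral = config@noncfIntegral[[cc]] *
        exp(stats::rnorm(n, -config@noncfJitterSd^2 / 2, config@noncfJitterSd)),
      stringsAsFactors = FALSE)
  }
  evoked <- do.call(rbind, evokedList)
  events <- rbind(spontDf, evoked)
  events <- events[order(events$dendrite_id, events$time_ms), , drop = FALSE]

  # refractory: evoked events win over spontaneous ones ----------------------
  events <- do.call(rbind, lapply(split(events, events$dendrite_id),
                                  .enforceRefractory,
                                  refractory = config@refractory))
  rownames(events) <- NULL

  noncf <- if (length(noncfList)) do.call(rbind, noncfList) else
    data.frame(trial_id = integer(0), dendrite_id = integer(0),
               condition = character(0), onset_ms = numeric(0),
               rise_ms = numeric(0), integral = numeric(0))

  new("GroundTruth", events = events, noncf = noncf,
      sharedState = sharedState, roiPositions = positions,
      profiles = profiles, dendriteType = type, lateralityType = latType)
}

# Greedy refractory enforcement; evoked events take precedence.
.enforceRefractory <- function(ev, refractory) {
  if (nrow(ev) < 2L) return(ev)
  ev <- ev[order(ev$time_ms), , drop = FALSE]
  keep <- rep(TRUE, nrow(ev))
  last <- 1L
  for (i in 2L:nrow(ev)) {
    if (ev$time_ms[i] - ev$time_ms[last] >= refractory) {
      last <- i
    } else if (ev$origin[i] == "evoked" && ev$origin[last] == "spontaneous") {
      keep[last] <- FALSE
      last <- i
    } else {
      keep[i] <- FALSE
    }
  }
  ev[keep, , drop = FALSE]
}

# Closed-form extra synchrony of the generator for a pair with marginals
# p1, p2 under shared-state probability q (used as a test oracle).
generatorExtraSynchrony <- function(p1, p2, q, boost = 1.5) {
  r1 <- .sharedRates(p1, q, boost)
  r2 <- .sharedRates(p2, q, boost)
  q * (1 - q) * (r1[["hi"]] - r1[["lo"]]) * (r2[["hi"]] - r2[["lo"]])
}
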