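# Coactivation, joint probabilities, extra synchrony, distance correlation.

.protFor <- function(nTrials = 10L) {
  makeProtocol(generatorConfig(trialsPerCondition = nTrials,
                               latencyCalibration = "population"),
               "duration")
}

test_that("coactivation is the fraction of responsive dendrites with an event", {
  prot <- .protFor(1L)
  t1 <- prot@trials$trial_id[1]
  on1 <- prot@trials$onset_s[1] * 1000
  ev <- makeEvents(1:3, rep(on1 + 100, 3), label = "evoked", trial = t1,
                   condition = prot@trials$condition[1])
  co <- coactivationFraction(ev, prot, responsive = 1:6)
  expect_equal(co$perTrial$fraction[co$perTrial$trial_id == t1], 0.5)
  # trials without events have fraction 0
  expect_true(all(co$perTrial$fraction[co$perTrial$trial_id != t1] == 0))
  expect_error(coactivationFraction(ev, prot, responsive = 1:5),
               "excluded")
})

test_that("joint probabilities: saturation and disjoint responses", {
  prot <- .protFor(2L)
  tr <- prot@trials
  d1T <- tr$trial_id[tr$condition == "d1"]
  onset <- function(tid) tr$onset_s[match(tid, tr$trial_id)] * 1000
  # both dendrites respond on every trial -> measured = independent = 1
  evAll <- rbind(
    makeEvents(1, onset(tr$trial_id) * 1 + 100, label = "evoked",
               trial = tr$trial_id, condition = tr$condition),
    makeEvents(2, onset(tr$trial_id) + 101, label = "evoked",
               trial = tr$trial_id, condition = tr$condition))
  pj <- pairJointProbability(evAll, prot, dendrites = 1:2)
  d1row <- pj[pj$condition == "d1", ]
  expect_equal(d1row$measured, 1)
  expect_equal(d1row$independent, 1)
  # perfectly disjoint responses: P_i = P_j = 0.5, measured 0, independent .25
  evDisj <- rbind(
    makeEvents(1, onset(d1T[1]) + 100, label = "evoked", trial = d1T[1],
               condition = "d1"),
    makeEvents(2, onset(d1T[2]) + 100, label = "evoked", trial = d1T[2],
               condition = "d1"))
  pj2 <- pairJointProbability(evDisj, prot, dendrites = 1:2)
  d1row2 <- pj2[pj2$condition == "d1", ]
  expect_equal(d1row2$measured, 0)
  expect_equal(d1row2$independent, 0.25)
})

test_that("a perfectly yoked pair at P = 0.5 has 25% extra synchrony", {
  ps <- data.frame(i = 1, j = 2, condition = "d1",
                   measured = 0.5, independent = 0.25)
  xs <- extraSynchrony(ps)
  expect_equal(xs$mean_pct, 25)
})

test_that("independent generator has no extra synchrony; shared drive creates it", {
  pooled <- c()
  pj0 <- NULL
  for (seed in c(17L, 18L, 19L)) {
    cfg0 <- generatorConfig(nDendrites = 8L, trialsPerCondition = 35L,
                            sharedDriveProb = 0, spontSyncScale = 0,
                            gradedFraction = 1, seed = seed,
                            latencyCalibration = "population")
    x0 <- simulateExperiment(cfg0, "duration")
    ev0 <- classifyEvents(detectEvents(x0), protocol(x0))
    pjs <- pairJointProbability(ev0, protocol(x0), dendrites = 1:8)
    if (is.null(pj0)) {
      pj0 <- pjs
      # keep one run for the Frechet check and marginals below
      mrg <- eventProbability(ev0, protocol(x0), nDendrites = 8)
    }
    pooled <- c(pooled, 100 * (pjs$measured - pjs$independent)[pjs$condition != "sp"])
  }
  expect_lt(abs(mean(pooled)), 2 * sd(pooled) / sqrt(length(pooled)))

  # Frechet bounds hold for every measured joint probability
  for (r in seq_len(nrow(pj0))) {
    cc <- pj0$condition[r]
    pi <- mrg$prob[mrg$dendrite_id == pj0$i[r] & mrg$condition == cc]
    pk <- mrg$prob[mrg$dendrite_id == pj0$j[r] & mrg$condition == cc]
    expect_gte(pj0$measured[r], max(0, pi + pk - 1) - 1e-12)
    expect_lte(pj0$measured[r], min(pi, pk) + 1e-12)
  }

  # with shared drive, measured exceeds independent on average, matching
  # the generator's closed form q(1-q)(pHi-pLo)^2
  cfg1 <- generatorConfig(nDendrites = 8L, trialsPerCondition = 70L,
                          sharedDriveProb = 0.4, spontSyncScale = 0,
                          gradedFraction = 1, seed = 19L,
                          latencyCalibration = "population")
  x1 <- simulateExperiment(cfg1, "duration")
  ev1 <- classifyEvents(detectEvents(x1), protocol(x1))
  pj1 <- pairJointProbability(ev1, protocol(x1), dendrites = 1:8)
  for (cc in c("d1", "d4")) {
    p <- cfg1@evokedProb[[cc]]
    expected <- 100 * cfcalcium:::generatorExtraSynchrony(p, p, 0.4)
    got <- mean(100 * (pj1$measured - pj1$independent)[pj1$condition == cc])
    expect_gt(got, 0)
    expect_lt(abs(got - expected), 6)  # sampling noise at 70 trials, 28 pairs
  }
})

test_that("extra synchrony grows with the shared-drive gradient", {
  cfg <- generatorConfig(nDendrites = 8L, trialsPerCondition = 70L,
                         gradedFraction = 1, seed = 23L,
                         evokedProb = 0.6,
                         sharedDriveProb = c(d1 = 0.05, d2 = 0.15, d3 = 0.3,
                                             d4 = 0.45, p1 = 0.1, p2 = 0.3),
                         latencyCalibration = "population")
  x <- simulateExperiment(cfg, "duration")
  ev <- classifyEvents(detectEvents(x), protocol(x))
  pj <- pairJointProbability(ev, protocol(x), dendrites = 1:8)
  xs <- extraSynchrony(pj[pj$condition != "sp", ])
  vals <- xs$mean_pct[match(c("d1", "d4"), xs$condition)]
  expect_gt(vals[2], vals[1])
})

test_that("spontaneous correlation decays with distance; shuffles kill it", {
  cfg <- generatorConfig(nDendrites = 10L, trialsPerCondition = 0L,
                         spontDuration = 400, spontSyncScale = 50,
                         dendriteSpacing = 20, seed = 29L,
                         latencyCalibration = "population")
  p0 <- makeProtocol(cfg, "duration")
  tr <- simulateEvents(cfg, p0)
  ev <- tr@events
  ev$label <- "spontaneous"
  ev$peak_time_ms <- ev$time_ms + 10
  sc <- spontDistanceCorrelation(ev, unname(tr@roiPositions), 400,
                                 nShuffles = 30, seed = 2)
  near <- sc$pairs$r[sc$pairs$distance_um <= 40]
  far <- sc$pairs$r[sc$pairs$distance_um >= 120]
  expect_gt(mean(near), mean(far))
  expect_gt(mean(near), 0.05)
  expect_lt(abs(mean(sc$pairs$r_shuffled)), 0.02)

  # identical rasters at distance 0 correlate perfectly
  ev2 <- rbind(ev[ev$dendrite_id == 1, ],
               transform(ev[ev$dendrite_id == 1, ], dendrite_id = 2))
  sc2 <- spontDistanceCorrelation(ev2, c(0, 0), 400, nShuffles = 2, seed = 2)
  expect_equal(sc2$pairs$r, 1)
})
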