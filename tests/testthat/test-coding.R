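# Probability coding, categorization, latency statistics, laterality.

test_that("event probability is the fraction of trials with an evoked event", {
  cfg <- generatorConfig(trialsPerCondition = 35L,
                         latencyCalibration = "population")
  prot <- makeProtocol(cfg, "duration")
  d1Trials <- prot@trials$trial_id[prot@trials$condition == "d1"]
  hits <- d1Trials[1:21]
  ev <- makeEvents(1, prot@trials$onset_s[match(hits, prot@trials$trial_id)] * 1000 + 100,
                   label = "evoked", trial = hits, condition = "d1")
  pr <- eventProbability(ev, prot, nDendrites = 1)
  expect_equal(pr$prob[pr$condition == "d1"], 21 / 35)
  expect_equal(pr$prob[pr$condition == "d2"], 0)
  expect_equal(pr$prob[pr$condition == "sp"], 0)
  # no events at all
  pr0 <- eventProbability(emptyEvents(), prot, nDendrites = 2)
  expect_true(all(pr0$prob == 0))
})

test_that("probability recovery matches the generator profile (binomial CI)", {
  cfg <- generatorConfig(nDendrites = 6L, trialsPerCondition = 35L,
                         gradedFraction = 1, sharedDriveProb = 0,
                         evokedProb = c(d1 = 0.3, d2 = 0.5, d3 = 0.7, d4 = 0.9),
                         seed = 21L, latencyCalibration = "population")
  x <- simulateExperiment(cfg, "duration")
  ev <- classifyEvents(detectEvents(x), protocol(x))
  pr <- eventProbability(ev, protocol(x), nDendrites = 6)
  for (cc in c("d1", "d2", "d3", "d4")) {
    p <- cfg@evokedProb[[cc]]
    est <- mean(pr$prob[pr$condition == cc])
    # across 6 dendrites x 35 trials
    expect_lt(abs(est - p), 3 * sqrt(p * (1 - p) / (6 * 35)))
  }
})

test_that("dendrite categorization separates graded from threshold profiles", {
  expect_equal(categorizeDendrite(c(0.2, 0.4, 0.6, 0.8), sp = 0)$category, 1L)
  r <- categorizeDendrite(c(0.05, 0.05, 0.7, 0.7), sp = 0)
  expect_equal(r$category, 4L)
  expect_equal(r$threshold, 3L)
  z <- categorizeDendrite(c(0, 0, 0, 0), sp = 0)
  expect_equal(z$category, 5L)
  expect_true(z$unresponsive)
  # exhaustive: every exact step position is recovered
  for (k in 1:4) {
    probs <- ifelse(seq_len(4) >= k, 0.7, 0.05)
    expect_equal(categorizeDendrite(probs, sp = 0.05)$category,
                 1L + k, info = paste("step at", k))
  }
})

test_that("graded fraction is recovered from a precisely sampled generator", {
  cfg <- generatorConfig(nDendrites = 60L, trialsPerCondition = 200L,
                         gradedFraction = 0.58, sharedDriveProb = 0,
                         seed = 5L, latencyCalibration = "population")
  prot <- makeProtocol(cfg, "duration")
  truth <- simulateEvents(cfg, prot)
  ev <- truth@events[truth@events$origin == "evoked", ]
  ev$label <- "evoked"
  ev$peak_time_ms <- ev$time_ms + 10
  cats <- vapply(seq_len(60), function(d) {
    pr <- vapply(c("d1", "d2", "d3", "d4"), function(cc)
      length(unique(ev$trial_id[ev$dendrite_id == d & ev$condition == cc])) / 200,
      numeric(1))
    categorizeDendrite(pr, sp = 0.1, nTrials = 200)$category
  }, integer(1))
  est <- mean(cats == 1L)
  expect_lt(abs(est - 0.58), 3 * sqrt(0.58 * 0.42 / 60))
  # and the assignments agree with the generator's own dendrite types
  expect_gt(mean((cats == 1L) == (truth@dendriteType == "graded")), 0.9)
})

test_that("latency statistics: hand-computed medians and MADs", {
  ev <- makeEvents(1, c(1060, 1070, 1080), label = "evoked", trial = 1L,
                   condition = "d1", latency = c(60, 70, 80))
  ls <- latencyStats(ev, minEvents = 1L)
  expect_equal(ls$perDendrite$median_ms, 70)
  expect_equal(ls$perDendrite$mad_ms, 10)
  ev1 <- makeEvents(1, 1060, label = "evoked", trial = 1L, condition = "d1",
                    latency = 60)
  expect_equal(latencyStats(ev1, minEvents = 1L)$perDendrite$mad_ms, 0)
})

test_that("MAD is translation invariant and scales with dispersion", {
  base <- c(55, 61, 70, 82, 95, 120)
  m0 <- cfcalcium:::jitterMad(base)
  expect_equal(cfcalcium:::jitterMad(base + 13), m0)
  expect_equal(cfcalcium:::jitterMad(3 * base), 3 * m0)
})

test_that("latency-interval counts use half-open windows", {
  ev <- makeEvents(1, c(1100, 1101, 1102), label = "evoked", trial = 1L,
                   condition = "d1", latency = c(74.9, 75, 10))
  lw <- latencyWindowCounts(ev)
  expect_equal(lw$count[lw$window == "[0,75)"], 2L)   # 74.9 and 10
  expect_equal(lw$count[lw$window == "[75,150)"], 1L) # 75.0
})

test_that("longer airpuffs add late-window events in the generator", {
  cfg <- generatorConfig(nDendrites = 8L, trialsPerCondition = 35L,
                         gradedFraction = 1, seed = 31L,
                         latencyCalibration = "population")
  x <- simulateExperiment(cfg, "duration")
  ev <- estimateLatencies(x, classifyEvents(detectEvents(x), protocol(x)))
  lw <- latencyWindowCounts(ev)
  late <- function(cc) sum(lw$count[lw$condition == cc & lw$window == "[75,150)"])
  # d4 has both more events and later latencies than d1
  expect_gt(late("d4"), late("d1"))
})

test_that("laterality is classified from ipsi and contra responses", {
  cfg <- generatorConfig(trialsPerCondition = 20L,
                         latencyCalibration = "population")
  prot <- makeProtocol(cfg, "duration", lateralities = c("ipsi", "contra"))
  tr <- prot@trials
  ipsiT <- tr$trial_id[tr$laterality == "ipsi" & tr$condition == "d4"]
  # dendrite 1 responds to 80% of ipsi d4 trials only; dendrite 2 never
  hits <- ipsiT[seq_len(round(0.8 * length(ipsiT)))]
  ev <- makeEvents(1, tr$onset_s[match(hits, tr$trial_id)] * 1000 + 100,
                   label = "evoked", trial = hits, condition = "d4")
  cl <- classifyLaterality(ev, prot, nDendrites = 2)
  expect_equal(cl$laterality, c("ipsi_specific", "unresponsive"))
  # protocol without contra trials is an error
  protI <- makeProtocol(cfg, "duration", lateralities = "ipsi")
  expect_error(classifyLaterality(ev, protI), "laterality undefined")
})

test_that("bilateral dendrites are recovered from simulated contra trials", {
  cfg <- generatorConfig(nDendrites = 10L, trialsPerCondition = 20L,
                         bilateralFraction = 1, gradedFraction = 1,
                         sharedDriveProb = 0, seed = 13L,
                         latencyCalibration = "population")
  x <- simulateExperiment(cfg, "duration", lateralities = c("ipsi", "contra"))
  ev <- classifyEvents(detectEvents(x), protocol(x))
  cl <- classifyLaterality(ev, protocol(x))
  expect_gte(mean(cl$laterality == "bilateral"), 0.9)
})
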