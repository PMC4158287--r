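# Synthetic-data generator: protocols, ground truth, rendering.

test_that("generatorConfig validates its invariants", {
  expect_s4_class(generatorConfig(), "GeneratorConfig")
  expect_error(generatorConfig(evokedProb = c(d1 = 1.2)), "0, 1")
  expect_error(generatorConfig(evokedProb = c(d1 = 0.9, d2 = 0.2)),
               "non-decreasing")
  expect_error(generatorConfig(spontRate = -1), "positive")
  expect_error(generatorConfig(refractory = 5000), "inter-trial")
  expect_error(generatorConfig(bogus = 1), "unknown configuration")
})

test_that("config round-trips through YAML and JSON", {
  cfg <- generatorConfig(nDendrites = 3L, evokedProb = c(d2 = 0.5))
  for (ext in c("yaml", "json")) {
    f <- file.path(tempdir(), paste0("cfg.", ext))
    writeGeneratorConfig(cfg, f)
    cfg2 <- readGeneratorConfig(f)
    expect_equal(cfg2@evokedProb, cfg@evokedProb)
    expect_equal(cfg2@nDendrites, cfg@nDendrites)
    expect_equal(cfg2@latencyMedian, cfg@latencyMedian)
  }
})

test_that("duration protocol has 35 trials of each of 4 conditions", {
  p <- makeProtocol(generatorConfig(), "duration")
  expect_equal(nrow(p@trials), 140L)
  expect_equal(sort(unique(p@trials$condition)), c("d1", "d2", "d3", "d4"))
  expect_true(all(table(p@trials$condition) == 35L))
  expect_true(all(diff(p@trials$onset_s) >= 4 - 1e-9))
})

test_that("protocol edge cases: empty schedule, onset arithmetic, bad mode", {
  p0 <- makeProtocol(generatorConfig(trialsPerCondition = 0L), "duration")
  expect_equal(nrow(p0@trials), 0L)
  # 2 x 10 pressure trials at 4 s ITI starting at 0: last onset = 19 * 4 s
  pp <- makeProtocol(generatorConfig(trialsPerCondition = 10L), "pressure",
                     firstOnset = 0)
  expect_equal(nrow(pp@trials), 20L)
  expect_equal(max(pp@trials$onset_s), 76)
  expect_error(makeProtocol(generatorConfig(), "sideways"), "invalid mode")
  # CSV round trip
  f <- file.path(tempdir(), "protocol.csv")
  writeProtocol(pp, f)
  pp2 <- readProtocol(f, iti = 4, mode = "pressure")
  expect_equal(pp2@trials$onset_s, pp@trials$onset_s)
  expect_equal(pp2@trials$condition, pp@trials$condition)
})

test_that("latency distribution solver hits median and MAD exactly", {
  for (tgt in list(c(67.1, 23.3), c(80.9, 18.0))) {
    fit <- cfcalcium:::solveLatencyDist(tgt[1], tgt[2], 40, 190)
    st <- cfcalcium:::.latencyStats(fit)
    expect_equal(unname(st["median"]), tgt[1], tolerance = 1e-6)
    expect_equal(unname(st["mad"]), tgt[2], tolerance = 1e-6)
    # large-sample simulation oracle
    set.seed(11)
    x <- cfcalcium:::rLatency(2e5, fit)
    expect_true(all(x >= 40 & x <= 190))
    expect_equal(median(x), tgt[1], tolerance = 0.02)
    expect_equal(median(abs(x - median(x))), tgt[2], tolerance = 0.02)
  }
  expect_error(cfcalcium:::solveLatencyDist(67.1, 80, 40, 190), "infeasible")
  expect_error(cfcalcium:::solveLatencyDist(67.1, 29, 40, 190), "infeasible")
})

test_that("spontaneous rate is Poisson-consistent and evoked marginals are calibrated", {
  cfg <- generatorConfig(nDendrites = 20L, trialsPerCondition = 0L,
                         spontDuration = 600, spontSyncScale = 0,
                         latencyCalibration = "population")
  p0 <- makeProtocol(cfg, "duration")
  tr <- simulateEvents(cfg, p0)
  counts <- table(factor(tr@events$dendrite_id, levels = 1:20))
  rate <- mean(counts) / 600
  # mean of 20 Poisson(0.7 * 600) counts: SE = sqrt(0.7/600/20)
  expect_lt(abs(rate - 0.7), 3 * sqrt(0.7 / (600 * 20)))

  # marginal evoked frequency equals the dendrite's profile despite the
  # shared facilitation state
  cfg2 <- generatorConfig(nDendrites = 30L, trialsPerCondition = 60L,
                          gradedFraction = 1, sharedDriveProb = 0.4,
                          latencyCalibration = "population")
  p2 <- makeProtocol(cfg2, "duration")
  tr2 <- simulateEvents(cfg2, p2)
  ev2 <- tr2@events[tr2@events$origin == "evoked", ]
  for (cc in c("d1", "d4")) {
    p <- cfg2@evokedProb[[cc]]
    k <- sum(ev2$condition == cc)
    n <- 30L * 60L
    # the shared facilitation state correlates dendrites within a trial;
    # the CI needs the design effect 1 + (nDendrites - 1) * rho with rho
    # from the generator's closed-form pair covariance
    rho <- cfcalcium:::generatorExtraSynchrony(p, p, 0.4) / (p * (1 - p))
    se <- sqrt(p * (1 - p) / n * (1 + (30 - 1) * rho))
    expect_lt(abs(k / n - p), 3 * se)
  }
})

test_that("ground truth respects refractory and the evoked-latency support", {
  tr <- groundTruth(smallExperiment())
  for (d in unique(tr@events$dendrite_id)) {
    tms <- sort(tr@events$time_ms[tr@events$dendrite_id == d])
    if (length(tms) > 1L) expect_true(all(diff(tms) >= 200))
  }
  lat <- tr@events$latency_ms[tr@events$origin == "evoked"]
  expect_true(all(lat >= 40 & lat < 190))
})

test_that("saturated evoked probability coactivates every dendrite", {
  cfg <- generatorConfig(nDendrites = 5L, trialsPerCondition = 1L,
                         evokedProb = 1, sharedDriveProb = 0,
                         gradedFraction = 1,
                         latencyCalibration = "population")
  p <- makeProtocol(cfg, "duration")
  tr <- simulateEvents(cfg, p)
  ev <- tr@events[tr@events$origin == "evoked", ]
  for (tid in p@trials$trial_id)
    expect_setequal(ev$dendrite_id[ev$trial_id == tid], 1:5)
})

test_that("generator is deterministic given config and seed", {
  cfg <- generatorConfig(nDendrites = 3L, trialsPerCondition = 5L,
                         latencyCalibration = "population")
  p <- makeProtocol(cfg, "duration")
  t1 <- simulateEvents(cfg, p)
  t2 <- simulateEvents(cfg, p)
  expect_identical(t1@events, t2@events)
  expect_identical(t1@noncf, t2@noncf)
  x1 <- renderTraces(t1, cfg, p)
  x2 <- renderTraces(t2, cfg, p)
  expect_identical(assay(x1, "dff"), assay(x2, "dff"))
})

test_that("rendered kernel has the configured peak and half-decay", {
  x <- singleKernelTrace(ampFactor = 1.3)
  v <- assay(x, "dff")[1, ]
  cfg <- metadata(x)$config
  expect_equal(max(v), 1.3 * cfg@eventAmp, tolerance = 1e-3)
  pk <- which.max(v)
  expect_equal(pk - 1 - 500, 10, tolerance = 1.5)  # peak ~10 ms after onset
  hd <- halfDecayTime(v, pk, 1)
  expect_equal(hd, 74, tolerance = 0.03)
  # flat at F0 away from the event
  expect_equal(unname(assay(x, "F")[1, 100]), cfg@f0)
})

test_that("rendering is linear: two events superpose exactly", {
  mk <- function(times) {
    cfg <- generatorConfig(noiseSd = 0, nDendrites = 1L,
                           trialsPerCondition = 0L, spontDuration = 3,
                           latencyCalibration = "population")
    truth <- new("GroundTruth",
                 events = data.frame(dendrite_id = 1L, time_ms = times,
                                     amp = 1, origin = "spontaneous",
                                     trial_id = NA_integer_,
                                     condition = NA_character_,
                                     latency_ms = NA_real_),
                 noncf = data.frame(trial_id = integer(0),
                                    dendrite_id = integer(0),
                                    condition = character(0),
                                    onset_ms = numeric(0),
                                    rise_ms = numeric(0),
                                    integral = numeric(0)),
                 sharedState = data.frame(trial_id = integer(0),
                                          shared = logical(0)),
                 roiPositions = c(den1 = 0), profiles = matrix(0, 1, 1),
                 dendriteType = "graded", lateralityType = "ipsi")
    p <- makeProtocol(cfg, "duration")
    assay(renderTraces(truth, cfg, p, noise = FALSE), "dff")[1, ]
  }
  both <- mk(c(400, 700))
  a <- mk(400)
  b <- mk(700)
  expect_equal(both, a + b, tolerance = 1e-12)
})

test_that("movie rendering round-trips through masks", {
  cfg <- generatorConfig(nDendrites = 3L, trialsPerCondition = 2L,
                         noiseSd = 0, latencyCalibration = "population")
  x <- binToFrames(simulateExperiment(cfg, "duration", noise = FALSE))
  mv <- renderMovie(x, cfg, pixelNoiseSd = 0)
  expect_length(mv$masks, 3L)
  rec <- extractRoiFluorescence(mv$movie, mv$masks)
  expect_equal(rec, unname(assay(x, "F")), tolerance = 1e-9)

  # 15 dendrites fit a 32 x 128 field as disjoint stripes
  cfg15 <- generatorConfig(nDendrites = 15L, trialsPerCondition = 0L,
                           spontDuration = 2, noiseSd = 0,
                           latencyCalibration = "population")
  p0 <- makeProtocol(cfg15, "duration")
  x15 <- binToFrames(renderTraces(simulateEvents(cfg15, p0), cfg15, p0,
                                  noise = FALSE))
  mv15 <- renderMovie(x15, cfg15, pixelNoiseSd = 0)
  pix <- unlist(lapply(mv15$masks, function(m) paste(m[, 1], m[, 2])))
  expect_length(mv15$masks, 15L)
  expect_false(any(duplicated(pix)))

  # too many dendrites for the field
  cfg99 <- generatorConfig(nDendrites = 99L, trialsPerCondition = 0L,
                           spontDuration = 1, noiseSd = 0,
                           latencyCalibration = "population")
  p99 <- makeProtocol(cfg99, "duration")
  x99 <- binToFrames(renderTraces(simulateEvents(cfg99, p99), cfg99, p99,
                                  noise = FALSE))
  expect_error(renderMovie(x99, cfg99), "stripes")
})

test_that("mask averaging shrinks pixel noise as 1/sqrt(mask size)", {
  cfg <- generatorConfig(nDendrites = 1L, trialsPerCondition = 0L,
                         spontDuration = 6, noiseSd = 0,
                         latencyCalibration = "population")
  p0 <- makeProtocol(cfg, "duration")
  x <- binToFrames(renderTraces(simulateEvents(cfg, p0), cfg, p0,
                                noise = FALSE))
  mv <- renderMovie(x, cfg, pixelNoiseSd = 5, seed = 3)
  res <- extractRoiFluorescence(mv$movie, mv$masks)[1, ] - assay(x, "F")[1, ]
  nPix <- nrow(mv$masks[[1]])
  expect_equal(sd(res), 5 / sqrt(nPix), tolerance = 0.2)
})

test_that("TIFF and mask files round-trip", {
  cfg <- generatorConfig(nDendrites = 2L, trialsPerCondition = 0L,
                         spontDuration = 3, noiseSd = 0,
                         latencyCalibration = "population")
  p0 <- makeProtocol(cfg, "duration")
  x <- binToFrames(renderTraces(simulateEvents(cfg, p0), cfg, p0,
                                noise = FALSE))
  tf <- file.path(tempdir(), "movie.tif")
  mf <- file.path(tempdir(), "masks.csv")
  mv <- renderMovie(x, cfg, file = tf, maskFile = mf, pixelNoiseSd = 0)
  movie <- readMovie(tf) * mv$scale
  masks <- readMasks(mf)
  rec <- extractRoiFluorescence(movie, masks)
  # 16-bit quantization bounds the round-trip error
  expect_equal(rec, unname(assay(x, "F")), tolerance = 1e-3)
})
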