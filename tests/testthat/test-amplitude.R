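# Event sizes, sp reference, enhancement, non-CF extraction, linearity.

test_that("event integral: rectangle area and analytic kernel integral", {
  expect_equal(eventIntegral(rep(1, 300), 1, 50), 100)
  # window exceeding the trace is flagged
  expect_true(is.na(eventIntegral(rep(1, 80), 1, 50)))

  x <- singleKernelTrace()
  v <- assay(x, "dff")[1, ]
  pk <- which.max(v)
  params <- cfcalcium:::cfKernelParams(10, 74)
  analytic <- 0.3 * cfcalcium:::cfKernelIntegral(10, 110, params)
  expect_equal(eventIntegral(v, 1, pk), analytic, tolerance = 0.01)
})

test_that("normalization closure: spontaneous integrals average exactly 1", {
  x <- normalizeExperiment(smallExperiment(), smallEvents())
  sz <- eventSizes(x, smallEvents())
  ev <- sz$events
  for (d in unique(ev$dendrite_id)) {
    v <- ev$norm_integral[ev$dendrite_id == d & ev$label == "spontaneous" &
                            is.finite(ev$norm_integral)]
    if (length(v)) expect_equal(mean(v), 1, tolerance = 1e-9)
  }
})

test_that("multi-event trials are excluded at < 100 ms separation", {
  e2 <- makeEvents(1, c(1080, 1160), label = "evoked", trial = 1L,
                   condition = "d1")
  r2 <- excludeMultiEventTrials(e2)
  expect_equal(nrow(r2$excluded), 1L)
  expect_true(all(!r2$keep[e2$label == "evoked"]))
  e3 <- makeEvents(1, c(1080, 1200), label = "evoked", trial = 1L,
                   condition = "d1")
  r3 <- excludeMultiEventTrials(e3)
  expect_null(r3$excluded)
  expect_true(all(r3$keep))
})

test_that("sp reference peak reflects latency jitter", {
  x <- singleKernelTrace()
  v <- assay(x, "dff")[1, ]
  pk <- which.max(v)
  win <- 320
  me <- v[(pk - win):(pk + 2 * win)] / max(v)
  # identical latencies: no smearing, peak 1
  ref0 <- buildSpReference(me, win + 1L, rep(100, 20), 1)
  expect_equal(max(ref0), 1, tolerance = 1e-6)
  # latencies uniform over 100 ms: smeared, peak < 1
  set.seed(9)
  refU <- buildSpReference(me, win + 1L, runif(200, 50, 150), 1)
  expect_lt(max(refU), 0.85)
  # convolution oracle: the composite equals the average of shifted kernels
  lats <- seq(60, 140, by = 5)
  refG <- buildSpReference(me, win + 1L, lats, 1)
  tms <- attr(refG, "time_ms")
  oracle <- rowMeans(vapply(lats, function(L) {
    k <- numeric(length(tms))
    src <- round(tms - L) + win + 1L
    ok <- src >= 1L & src <= length(me)
    k[ok] <- me[src[ok]]
    k
  }, numeric(length(tms))))
  expect_equal(as.numeric(refG), oracle, tolerance = 1e-9)
})

test_that("additive regime: enhancement equals the non-CF signal (gain 1)", {
  m <- .ampPairs(c(3L, 7L, 11L), eventGain = 1)
  dd <- m$integral.x - m$integral.y
  # pooled over replicates, dendrites and conditions: no systematic
  # difference under the additive generator
  expect_lt(abs(mean(dd)), 2 * sd(dd) / sqrt(length(dd)))
})

test_that("supralinearity flag fires only where event gain exceeds 1", {
  m <- .ampPairs(c(3L, 7L, 11L),
                 eventGain = c(d1 = 1, d2 = 1, d3 = 1, d4 = 1.6,
                               p1 = 1, p2 = 1))
  # familywise check over the 4 conditions: Bonferroni-level flags
  lin <- linearityComparison(
    data.frame(dendrite_id = m$dendrite_id, condition = m$condition,
               integral = m$integral.x),
    data.frame(dendrite_id = m$dendrite_id, condition = m$condition,
               integral = m$integral.y),
    conf = 1 - 0.025 / 4)
  expect_true(lin$supralinear[lin$condition == "d4"])
  expect_false(any(lin$supralinear[lin$condition != "d4"]))
  # the d4 excess dwarfs the other conditions
  expect_gt(lin$diff_mean[lin$condition == "d4"],
            3 * max(abs(lin$diff_mean[lin$condition != "d4"])))
})

test_that("non-CF integrals: zero when disabled, linear in the generator", {
  r0 <- .ampRun(noncfIntegral = 0)
  expect_lt(abs(mean(r0$amp$noncf$integral)), 0.05)
  r1 <- .ampRun(noncfIntegral = c(d1 = 0.2, d2 = 0.3, d3 = 0.4, d4 = 0.5,
                                  p1 = 0.2, p2 = 0.4))
  r2 <- .ampRun(noncfIntegral = c(d1 = 0.4, d2 = 0.6, d3 = 0.8, d4 = 1.0,
                                  p1 = 0.4, p2 = 0.8))
  m1 <- mean(r1$amp$noncf$integral[r1$amp$noncf$condition == "d4"])
  m2 <- mean(r2$amp$noncf$integral[r2$amp$noncf$condition == "d4"])
  expect_equal(m2 / m1, 2, tolerance = 0.25)
})

test_that("non-CF rise time is recovered within one frame", {
  r <- .ampRun(evokedProb = c(d1 = 0.1, d2 = 0.1, d3 = 0.1, d4 = 0.1,
                              p1 = 0.1, p2 = 0.1))
  ncf <- r$amp$noncf
  d4 <- ncf[ncf$condition == "d4", ]
  sem <- sd(d4$rise_ms) / sqrt(nrow(d4))
  expect_lt(abs(mean(d4$rise_ms) - 148), 64 + 2 * sem)
  # graded ordering of rise times is preserved
  mr <- vapply(c("d1", "d4"), function(cc)
    mean(ncf$rise_ms[ncf$condition == cc]), numeric(1))
  expect_gt(mr["d4"], mr["d1"])
})

test_that("event gain scales the enhancement integral linearly", {
  # same seed: identical event times and integration windows, so the
  # enhancement integral must scale as (gain - 1)
  r2 <- .ampRun(eventGain = 1.2, noncfIntegral = 0)
  r4 <- .ampRun(eventGain = 1.4, noncfIntegral = 0)
  m2 <- mean(r2$amp$enhancement$integral)
  m4 <- mean(r4$amp$enhancement$integral)
  expect_gt(m2, 0)
  expect_equal(m4 / m2, 2, tolerance = 0.15)
  # and gain 1 with non-CF off leaves no enhancement
  r1 <- .ampRun(eventGain = 1, noncfIntegral = 0)
  expect_lt(abs(mean(r1$amp$enhancement$integral)), 0.05)
})
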