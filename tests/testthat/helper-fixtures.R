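# Shared fixtures, built once per test run.

suppressPackageStartupMessages(library(SummarizedExperiment))

.fixtures <- new.env(parent = emptyenv())

# a small dense-mode duration experiment with ground truth
smallExperiment <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- generatorConfig(nDendrites = 6L, trialsPerCondition = 10L,
                           nExperiments = 1L, seed = 7L,
                           latencyCalibration = "population")
    .fixtures$small <- simulateExperiment(cfg, "duration")
  }
  .fixtures$small
}

# classified + latency-annotated events of the small experiment
smallEvents <- function() {
  if (is.null(.fixtures$smallEvents)) {
    x <- smallExperiment()
    ev <- detectEvents(x)
    ev <- classifyEvents(ev, protocol(x))
    .fixtures$smallEvents <- estimateLatencies(x, ev)
  }
  .fixtures$smallEvents
}

# noiseless single-kernel trace at dense resolution
singleKernelTrace <- function(ampFactor = 1, onsetMs = 500, durMs = 2000,
                              res = 1) {
  cfg <- generatorConfig(noiseSd = 0, nDendrites = 1L,
                         trialsPerCondition = 0L,
                         spontDuration = durMs / 1000,
                         latencyCalibration = "population")
  truth <- new("GroundTruth",
               events = data.frame(dendrite_id = 1L, time_ms = onsetMs,
                                   amp = ampFactor, origin = "spontaneous",
                                   trial_id = NA_integer_,
                                   condition = NA_character_,
                                   latency_ms = NA_real_,
                                   stringsAsFactors = FALSE),
               noncf = data.frame(trial_id = integer(0),
                                  dendrite_id = integer(0),
                                  condition = character(0),
                                  onset_ms = numeric(0), rise_ms = numeric(0),
                                  integral = numeric(0)),
               sharedState = data.frame(trial_id = integer(0),
                                        shared = logical(0)),
               roiPositions = c(den1 = 0), profiles = matrix(0, 1, 1),
               dendriteType = "graded", lateralityType = "ipsi")
  prot <- makeProtocol(cfg, "duration")
  renderTraces(truth, cfg, prot, resolution = res, noise = FALSE)
}

# an empty classified-event table with the pipeline's columns
emptyEvents <- function() {
  data.frame(dendrite_id = integer(0), peak_index = integer(0),
             peak_time_ms = numeric(0), peak_amp = numeric(0),
             template_score = numeric(0), label = character(0),
             trial_id = integer(0), condition = character(0),
             laterality = character(0), onset_latency_ms = numeric(0),
             stringsAsFactors = FALSE)
}

# full size/enhancement/non-CF analysis of a fresh simulation; evoked
# probability 0.5 balances the evoked and no-event trial pools. Results
# are cached so property tests can share simulations.
.ampCache <- new.env(parent = emptyenv())
.ampRun <- function(..., seed = 3L, mode = "duration") {
  key <- paste(deparse(list(..., seed = seed, mode = mode)), collapse = "")
  if (!is.null(.ampCache[[key]])) return(.ampCache[[key]])
  args <- list(nDendrites = 10L, trialsPerCondition = 25L,
               gradedFraction = 1, evokedProb = 0.5,
               seed = seed, latencyCalibration = "population")
  over <- list(...)
  args[names(over)] <- over
  cfg <- do.call(generatorConfig, args)
  x <- simulateExperiment(cfg, mode)
  ev <- estimateLatencies(x, classifyEvents(detectEvents(x), protocol(x)))
  xn <- normalizeExperiment(x, ev)
  sz <- eventSizes(xn, ev)
  amp <- cfcalcium:::.amplitudeAnalysis(xn, sz$events, sz$spontMean,
                                        seed = seed)
  out <- list(cfg = cfg, x = x, ev = sz$events, amp = amp,
              spontMean = sz$spontMean)
  .ampCache[[key]] <- out
  out
}

# pool enhancement/non-CF pairs over replicate simulations, keeping
# replicate x dendrite cells distinct
.ampPairs <- function(seeds, ...) {
  do.call(rbind, lapply(seeds, function(s) {
    r <- .ampRun(..., seed = s)
    m <- merge(r$amp$enhancement[, c("dendrite_id", "condition", "integral")],
               r$amp$noncf[, c("dendrite_id", "condition", "integral")],
               by = c("dendrite_id", "condition"))
    m$dendrite_id <- paste(s, m$dendrite_id)
    m
  }))
}

# hand-built classified event rows
makeEvents <- function(dendrite, peakMs, label = "spontaneous",
                       trial = NA_integer_, condition = NA_character_,
                       latency = NA_real_, samplePeriod = 1) {
  data.frame(dendrite_id = dendrite, peak_index = round(peakMs / samplePeriod) + 1L,
             peak_time_ms = peakMs, peak_amp = 1, template_score = 1,
             label = label, trial_id = trial, condition = condition,
             laterality = "ipsi", onset_latency_ms = latency,
             stringsAsFactors = FALSE)
}
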