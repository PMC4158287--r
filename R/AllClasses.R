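#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom SummarizedExperiment assays<- rowData<- assay<-
NULL

.CONDITIONS <- c("d1", "d2", "d3", "d4", "p1", "p2")

# Evoked classification window on event peak times, ms after stimulus onset
# (half-open). A fixed analysis convention, not a tunable.
EVOKED_WINDOW_MS <- c(50, 200)

.checkCondMap <- function(x, name, probs = FALSE) {
  msg <- character(0)
  if (!all(.CONDITIONS %in% names(x)))
    msg <- c(msg, sprintf("'%s' must be named for conditions %s", name,
                          paste(.CONDITIONS, collapse = ", ")))
  else {
    if (any(!is.finite(x)))
      msg <- c(msg, sprintf("'%s' contains non-finite values", name))
    if (probs && any(x < 0 | x > 1))
      msg <- c(msg, sprintf("'%s' must lie in [0, 1]", name))
    if (!probs && any(x <= 0))
      msg <- c(msg, sprintf("'%s' must be strictly positive", name))
  }
  msg
}

#' GeneratorConfig: parameters of the synthetic two-photon recording
#'
#' Holds every tunable of the synthetic-data generator. The defaults (see
#' [generatorConfig()]) are calibrated to the published physiology of
#' climbing-fiber calcium events in awake-mouse Purkinje cell dendrites:
#' 64 ms frames over a 32 x 128 pixel field, 4 s inter-trial interval,
#' 35 trials per condition, ~0.7 Hz spontaneous event rate, 10 ms rise /
#' 74 ms decay half-time kernels, and per-condition evoked probability,
#' latency, amplitude-gain, shared-drive and non-CF parameters for the four
#' airpuff durations (d1-d4) and two pressures (p1-p2).
#'
#' @slot nExperiments,nDendrites simulated experiments and dendrites per
#'   experiment.
#' @slot framePeriod frame period, ms.
#' @slot movieShape pixel dimensions (rows, columns) of rendered movies.
#' @slot umPerPx mediolateral microns per movie pixel column.
#' @slot iti inter-trial interval, s.
#' @slot trialsPerCondition trials per condition per experiment.
#' @slot firstOnset onset time of the first trial, s.
#' @slot spontDuration recording duration when no protocol is supplied, s.
#' @slot spontRate spontaneous CF event rate per dendrite, Hz.
#' @slot refractory minimum separation of events in one dendrite, ms.
#' @slot kernelRise,kernelDecayHalf CF kernel time-to-peak and decay
#'   half-time, ms.
#' @slot eventAmp peak dF/F of a unit spontaneous event.
#' @slot ampJitterSd log-scale SD of per-event amplitude variability.
#' @slot evokedProb per-condition probability of an evoked event per
#'   dendrite (graded profile).
#' @slot latencyMedian,latencyMad per-condition onset-latency median and
#'   MAD, ms.
#' @slot latencyCalibration \code{"estimator"} (default): the latency
#'   distribution is solved so that the expected per-dendrite sample
#'   median/MAD at the configured trial counts equals the target, removing
#'   the small-sample bias the median estimator carries under skewed
#'   latency distributions; \code{"population"}: the population median/MAD
#'   equal the target exactly.
#' @slot eventGain per-condition multiplicative amplitude factor for evoked
#'   events (spontaneous = 1).
#' @slot noncfIntegral per-condition size of the slow non-CF component, in
#'   normalized dF/F-integral units.
#' @slot noncfRise per-condition time-to-peak of the non-CF component, ms.
#' @slot noncfJitterSd log-scale SD of per-trial non-CF amplitude.
#' @slot sharedDriveProb per-condition probability of the per-trial shared
#'   facilitation state that produces extra synchrony.
#' @slot spontSyncScale distance constant of shared spontaneous events, um.
#' @slot spontShare sharing probability of spontaneous events at zero
#'   mediolateral separation.
#' @slot dendriteSpacing mediolateral spacing of simulated dendrites, um.
#' @slot gradedFraction fraction of dendrites with a graded (rank-ordered)
#'   evoked-probability profile; the rest are threshold-like.
#' @slot bilateralFraction fraction of dendrites responsive to both
#'   lateralities when contra trials are simulated.
#' @slot noiseSd SD of additive Gaussian recording noise, dF/F units.
#' @slot renderResolution rendering step, ms (1 = dense; set to
#'   \code{framePeriod} for frame-resolution rendering).
#' @slot f0 baseline fluorescence, arbitrary units.
#' @slot seed integer RNG seed.
#' @export
setClass("GeneratorConfig", representation(
  nExperiments = "integer", nDendrites = "integer",
  framePeriod = "numeric", movieShape = "integer", umPerPx = "numeric",
  iti = "numeric", trialsPerCondition = "integer", firstOnset = "numeric",
  spontDuration = "numeric", spontRate = "numeric", refractory = "numeric",
  kernelRise = "numeric", kernelDecayHalf = "numeric",
  eventAmp = "numeric", ampJitterSd = "numeric",
  evokedProb = "numeric", latencyMedian = "numeric", latencyMad = "numeric",
  eventGain = "numeric", noncfIntegral = "numeric", noncfRise = "numeric",
  noncfJitterSd = "numeric", sharedDriveProb = "numeric",
  latencyCalibration = "character",
  spontSyncScale = "numeric", spontShare = "numeric",
  dendriteSpacing = "numeric", gradedFraction = "numeric",
  bilateralFraction = "numeric", noiseSd = "numeric",
  renderResolution = "numeric", f0 = "numeric", seed = "integer"
))

setValidity("GeneratorConfig", function(object) {
  msg <- character(0)
  for (nm in c("framePeriod", "iti", "spontDuration", "spontRate",
               "refractory", "kernelRise", "kernelDecayHalf", "eventAmp",
               "dendriteSpacing", "renderResolution", "f0", "umPerPx")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a positive scalar", nm))
  }
  for (nm in c("gradedFraction", "bilateralFraction", "spontShare")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("'%s' must lie in [0, 1]", nm))
  }
  if (object@spontSyncScale < 0) msg <- c(msg, "'spontSyncScale' must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (object@ampJitterSd < 0 || object@noncfJitterSd < 0)
    msg <- c(msg, "amplitude jitter SDs must be >= 0")
  msg <- c(msg,
           .checkCondMap(object@evokedProb, "evokedProb", probs = TRUE),
           .checkCondMap(object@sharedDriveProb, "sharedDriveProb", probs = TRUE),
           .checkCondMap(object@latencyMedian, "latencyMedian"),
           .checkCondMap(object@latencyMad, "latencyMad"),
           .checkCondMap(object@eventGain, "eventGain"),
           .checkCondMap(object@noncfRise, "noncfRise"))
  if (!all(.CONDITIONS %in% names(object@noncfIntegral)) ||
      any(object@noncfIntegral < 0))
    msg <- c(msg, "'noncfIntegral' must be named per condition and >= 0")
  if (all(.CONDITIONS %in% names(object@evokedProb))) {
    for (fam in list(c("d1", "d2", "d3", "d4"), c("p1", "p2"))) {
      p <- object@evokedProb[fam]
      if (any(diff(p) < 0))
        msg <- c(msg, "'evokedProb' must be non-decreasing with stimulus strength")
    }
  }
  if (object@refractory >= object@iti * 1000)
    msg <- c(msg, "'refractory' must be smaller than the inter-trial interval")
  if (!object@latencyCalibration %in% c("estimator", "population"))
    msg <- c(msg, "'latencyCalibration' must be 'estimator' or 'population'")
  if (length(object@movieShape) != 2L || any(object@movieShape < 1L))
    msg <- c(msg, "'movieShape' must be two positive pixel counts")
  if (length(msg)) msg else TRUE
})

#' StimulusProtocol: the trial schedule of one experiment
#'
#' A table of periocular-airpuff trials: trial id, onset time (s),
#' condition label (d1-d4 durations or p1-p2 pressures) and stimulated side
#' (ipsi/contra). Onsets are strictly increasing and separated by at least
#' the inter-trial interval.
#'
#' @slot trials data.frame with columns \code{trial_id}, \code{onset_s},
#'   \code{condition}, \code{laterality}.
#' @slot iti inter-trial interval, s.
#' @slot mode "duration" or "pressure".
#' @export
setClass("StimulusProtocol", representation(
  trials = "data.frame", iti = "numeric", mode = "character"
))

setValidity("StimulusProtocol", function(object) {
  tr <- object@trials
  need <- c("trial_id", "onset_s", "condition", "laterality")
  if (!all(need %in% names(tr)))
    return(paste("trials must have columns", paste(need, collapse = ", ")))
  if (nrow(tr) > 1L) {
    d <- diff(tr$onset_s)
    if (any(d <= 0)) return("trial onsets must be strictly increasing")
    if (any(d < object@iti - 1e-9))
      return("consecutive onsets must be separated by at least the ITI")
  }
  if (!object@mode %in% c("duration", "pressure", "none"))
    return("mode must be 'duration' or 'pressure'")
  TRUE
})

#' GroundTruth: injected activity of a simulated experiment
#'
#' Records everything the generator injected so that recovery by the
#' analysis pipeline can be scored: CF event times/amplitudes with their
#' spontaneous/evoked origin and true latency, the per-trial non-CF
#' components, the per-trial shared facilitation state, ROI positions and
#' the per-dendrite true response profiles.
#'
#' @slot events data.frame: \code{dendrite_id}, \code{time_ms} (event
#'   onset), \code{amp} (multiplicative amplitude factor),
#'   \code{origin} ("spontaneous"/"evoked"), \code{trial_id},
#'   \code{condition}, \code{latency_ms}.
#' @slot noncf data.frame of non-CF components per stimulated trial and
#'   dendrite: \code{trial_id}, \code{dendrite_id}, \code{condition},
#'   \code{onset_ms}, \code{rise_ms}, \code{integral}.
#' @slot sharedState data.frame: \code{trial_id}, \code{shared} (logical).
#' @slot roiPositions mediolateral position per dendrite, um.
#' @slot profiles matrix dendrite x condition of true evoked probabilities.
#' @slot dendriteType "graded" or "threshold" per dendrite.
#' @slot lateralityType "bilateral" or "ipsi" per dendrite.
#' @export
setClass("GroundTruth", representation(
  events = "data.frame", noncf = "data.frame", sharedState = "data.frame",
  roiPositions = "numeric", profiles = "matrix", dendriteType = "character",
  lateralityType = "character"
))

setValidity("GroundTruth", function(object) {
  ev <- object@events
  need <- c("dendrite_id", "time_ms", "amp", "origin", "trial_id",
            "condition", "latency_ms")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns", paste(need, collapse = ", ")))
  if (nrow(ev) && !all(ev$origin %in% c("spontaneous", "evoked")))
    return("event origin must be 'spontaneous' or 'evoked'")
  if (length(object@profiles) && any(object@profiles < 0 | object@profiles > 1))
    return("profiles must be probabilities")
  TRUE
})

#' CalciumExperiment: dendrite x time fluorescence container
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are dendrites (with
#' mediolateral positions in \code{rowData}), columns are time samples.
#' Assays hold raw fluorescence \code{"F"} and/or \code{"dff"} (and
#' \code{"ndff"} after spontaneous-peak normalization). Metadata carries the
#' sample period (ms), the acquisition frame period (ms), and, for
#' simulated data, the \linkS4class{StimulusProtocol},
#' \linkS4class{GroundTruth} and \linkS4class{GeneratorConfig}.
#'
#' @export
setClass("CalciumExperiment", contains = "SummarizedExperiment")

setValidity("CalciumExperiment", function(object) {
  md <- metadata(object)
  if (is.null(md$sample_period_ms) || md$sample_period_ms <= 0)
    return("metadata$sample_period_ms must be a positive sample period (ms)")
  if (is.null(md$frame_period_ms) || md$frame_period_ms <= 0)
    return("metadata$frame_period_ms must be a positive frame period (ms)")
  if (!any(c("F", "dff") %in% names(assays(object))))
    return("needs at least one of assays 'F' or 'dff'")
  TRUE
})

#' AnalysisReport: tables, statistical tests and run metadata
#'
#' @slot tables named list of per-figure data.frames (probability, latency,
#'   synchrony, size, non-CF, exclusions).
#' @slot tests data.frame of statistical test results
#'   (\code{name}, \code{statistic}, \code{df}, \code{p}).
#' @slot runMetadata list: seed, mode, config echo, exclusion log, versions.
#' @export
setClass("AnalysisReport", representation(
  tables = "list", tests = "data.frame", runMetadata = "list"
))
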