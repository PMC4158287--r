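#' @rdname CalciumExperiment-class
#' @param object,x a \linkS4class{CalciumExperiment}.
#' @export
setGeneric("samplePeriod", function(x) standardGeneric("samplePeriod"))

#' @rdname CalciumExperiment-class
#' @export
setGeneric("framePeriod", function(x) standardGeneric("framePeriod"))

#' @rdname CalciumExperiment-class
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' @rdname CalciumExperiment-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname CalciumExperiment-class
#' @export
setGeneric("roiPositions", function(x) standardGeneric("roiPositions"))

#' @rdname computeDff
#' @export
setGeneric("computeDff", function(x, ...) standardGeneric("computeDff"))

#' @rdname detectEvents
#' @export
setGeneric("detectEvents", function(x, ...) standardGeneric("detectEvents"))

#' @export
setMethod("samplePeriod", "CalciumExperiment",
          function(x) metadata(x)$sample_period_ms)

#' @export
setMethod("framePeriod", "CalciumExperiment",
          function(x) metadata(x)$frame_period_ms)

#' @export
setMethod("protocol", "CalciumExperiment", function(x) metadata(x)$protocol)

#' @export
setMethod("groundTruth", "CalciumExperiment", function(x) metadata(x)$truth)

#' @export
setMethod("roiPositions", "CalciumExperiment",
          function(x) rowData(x)$position_um)

#' @export
setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:", object@nExperiments, "experiment(s) x",
      object@nDendrites, "dendrites\n")
  cat("  frame", object@framePeriod, "ms | render", object@renderResolution,
      "ms | ITI", object@iti, "s |", object@trialsPerCondition,
      "trials/condition\n")
  cat("  spont", object@spontRate, "Hz | kernel", object@kernelRise, "/",
      object@kernelDecayHalf, "ms | noise sd", object@noiseSd, "\n")
  cat("  evoked prob:",
      paste(sprintf("%s=%.2f", names(object@evokedProb), object@evokedProb),
            collapse = " "), "\n")
})

#' @export
setMethod("show", "StimulusProtocol", function(object) {
  tr <- object@trials
  cat("StimulusProtocol (", object@mode, "): ", nrow(tr), " trials\n", sep = "")
  if (nrow(tr)) {
    tab <- table(tr$condition)
    cat("  conditions:",
        paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
    cat("  onsets", min(tr$onset_s), "-", max(tr$onset_s), "s, ITI",
        object@iti, "s\n")
  }
})

#' @export
setMethod("show", "GroundTruth", function(object) {
  ev <- object@events
  cat("GroundTruth:", nrow(ev), "events in", length(object@roiPositions),
      "dendrites\n")
  if (nrow(ev))
    cat("  ", sum(ev$origin == "spontaneous"), "spontaneous /",
        sum(ev$origin == "evoked"), "evoked;",
        nrow(object@noncf), "non-CF components\n")
})

#' @export
setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport:", length(object@tables), "tables,",
      nrow(object@tests), "statistical tests\n")
  cat("  tables:", paste(names(object@tables), collapse = ", "), "\n")
})
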