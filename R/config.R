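# Generator configuration: calibrated defaults and construction.

.defaultCondMaps <- function() {
  list(
    # graded evoked-probability profile; duration responses rise from weak
    # to strong airpuffs, higher pressure is more effective than lower
    evokedProb = c(d1 = 0.30, d2 = 0.45, d3 = 0.60, d4 = 0.75,
                   p1 = 0.40, p2 = 0.70),
    # onset-latency medians and jitter (MAD), ms
    latencyMedian = c(d1 = 67.1, d2 = 71.8, d3 = 78.8, d4 = 80.9,
                      p1 = 81.3, p2 = 79.6),
    latencyMad = c(d1 = 23.3, d2 = 21.1, d3 = 19.3, d4 = 18.0,
                   p1 = 21.0, p2 = 21.0),
    # evoked amplitude gain relative to spontaneous events
    eventGain = c(d1 = 1.05, d2 = 1.15, d3 = 1.25, d4 = 1.40,
                  p1 = 1.10, p2 = 1.30),
    # slow non-CF component: normalized dF/F-integral units and
    # time-to-peak from stimulus onset, ms
    noncfIntegral = c(d1 = 0.20, d2 = 0.35, d3 = 0.50, d4 = 0.65,
                      p1 = 0.25, p2 = 0.55),
    noncfRise = c(d1 = 73, d2 = 114, d3 = 130, d4 = 148,
                  p1 = 90, p2 = 120),
    # per-trial shared facilitation state probability (extra synchrony)
    sharedDriveProb = c(d1 = 0.15, d2 = 0.20, d3 = 0.25, d4 = 0.30,
                        p1 = 0.15, p2 = 0.25)
  )
}

#' Create a generator configuration
#'
#' Returns a \linkS4class{GeneratorConfig} populated with the calibrated
#' defaults of the study conditions this package emulates: 12 experiments of
#' 8 dendrites, 32 x 128 px movies at 64 ms/frame, 35 trials per airpuff
#' condition with a 4 s inter-trial interval, spontaneous CF events at
#' 0.7 Hz, transient kernels with 10 ms rise and 74 ms decay half-time,
#' per-condition evoked probability / onset latency (median, MAD) /
#' amplitude gain / non-CF size and rise time, a per-trial shared
#' facilitation state producing extra synchrony, and distance-dependent
#' sharing of spontaneous events. Any slot can be overridden by name;
#' per-condition maps may be overridden partially
#' (e.g. \code{evokedProb = c(d4 = 1)}).
#'
#' @param ... named overrides of any \linkS4class{GeneratorConfig} slot.
#' @return a validated \linkS4class{GeneratorConfig}.
#' @examples
#' cfg <- generatorConfig(nDendrites = 4L, trialsPerCondition = 10L)
#' cfg
#' @export
generatorConfig <- function(...) {
  maps <- .defaultCondMaps()
  args <- list(
    nExperiments = 12L, nDendrites = 8L,
    framePeriod = 64, movieShape = c(32L, 128L), umPerPx = 2,
    iti = 4, trialsPerCondition = 35L, firstOnset = 2,
    spontDuration = 600, spontRate = 0.7, refractory = 200,
    kernelRise = 10, kernelDecayHalf = 74,
    eventAmp = 0.30, ampJitterSd = 0.10,
    noncfJitterSd = 0.15, latencyCalibration = "estimator",
    spontSyncScale = 40, spontShare = 0.5,
    dendriteSpacing = 15, gradedFraction = 0.58,
    bilateralFraction = 0.5, noiseSd = 0.03,
    renderResolution = 1, f0 = 100, seed = 1L
  )
  args <- c(args, maps)
  over <- list(...)
  if (anyDuplicated(names(over)))
    stop("duplicated configuration field(s): ",
         paste(unique(names(over)[duplicated(names(over))]), collapse = ", "))
  unknown <- setdiff(names(over), names(args))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(over)) {
    if (nm %in% names(maps) && !is.null(names(over[[nm]]))) {
      m <- args[[nm]]
      bad <- setdiff(names(over[[nm]]), names(m))
      if (length(bad))
        stop("unknown condition label(s) in '", nm, "': ",
             paste(bad, collapse = ", "))
      m[names(over[[nm]])] <- over[[nm]]
      args[[nm]] <- m
    } else if (nm %in% names(maps)) {
      # unnamed vector: recycle over all conditions
      args[[nm]] <- stats::setNames(rep(over[[nm]],
                                        length.out = length(.CONDITIONS)),
                                    .CONDITIONS)
    } else {
      args[[nm]] <- over[[nm]]
    }
  }
  for (nm in c("nExperiments", "nDendrites", "trialsPerCondition", "seed"))
    args[[nm]] <- as.integer(args[[nm]])
  args$movieShape <- as.integer(args$movieShape)
  do.call(new, c(list("GeneratorConfig"), args))
}

#' Read or write a generator configuration
#'
#' Serializes a \linkS4class{GeneratorConfig} to YAML or JSON (chosen from
#' the file extension) and back.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param path file path ending in .yaml/.yml or .json.
#' @return \code{readGeneratorConfig} returns a
#'   \linkS4class{GeneratorConfig}; \code{writeGeneratorConfig} returns
#'   \code{path} invisibly.
#' @export
writeGeneratorConfig <- function(config, path) {
  stopifnot(is(config, "GeneratorConfig"))
  vals <- lapply(slotNames(config), function(nm) slot(config, nm))
  names(vals) <- slotNames(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lapply(vals, function(v) if (is.null(names(v))) v else as.list(v)), path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else stop("config path must end in .yaml, .yml or .json")
  invisible(path)
}

#' @rdname writeGeneratorConfig
#' @export
readGeneratorConfig <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config path must end in .yaml, .yml or .json")
  maps <- names(.defaultCondMaps())
  vals[maps] <- lapply(vals[maps], unlist)
  do.call(generatorConfig, vals)
}
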