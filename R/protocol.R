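# Stimulus protocols.

#' Build a randomized trial schedule
#'
#' Creates the trial table of one experiment: \code{trialsPerCondition}
#' trials of each condition in the chosen family (durations d1-d4 or
#' pressures p1-p2), in randomized order, with onsets spaced by the
#' inter-trial interval. With \code{lateralities = c("ipsi", "contra")}
#' every condition x side combination receives \code{trialsPerCondition}
#' trials.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param mode \code{"duration"} or \code{"pressure"}.
#' @param lateralities stimulated sides to include.
#' @param firstOnset onset of the first trial, s (defaults to
#'   \code{config@firstOnset}).
#' @param seed optional seed overriding \code{config@seed} for the trial
#'   ordering.
#' @return a \linkS4class{StimulusProtocol}.
#' @examples
#' p <- makeProtocol(generatorConfig(), "duration")
#' p  # 140 trials: 35 of each of d1-d4
#' @export
makeProtocol <- function(config, mode = c("duration", "pressure"),
                         lateralities = "ipsi", firstOnset = NULL,
                         seed = NULL) {
  stopifnot(is(config, "GeneratorConfig"))
  if (is.character(mode) && length(mode) == 1L &&
      !mode %in% c("duration", "pressure"))
    stop("invalid mode '", mode, "': must be 'duration' or 'pressure'")
  mode <- match.arg(mode)
  stopifnot(all(lateralities %in% c("ipsi", "contra")))
  if (is.null(firstOnset)) firstOnset <- config@firstOnset
  if (is.null(seed)) seed <- config@seed

  conds <- .conditionLevels(mode)
  cells <- expand.grid(condition = conds, laterality = lateralities,
                       stringsAsFactors = FALSE)
  labels <- cells[rep(seq_len(nrow(cells)), each = config@trialsPerCondition), ,
                  drop = FALSE]
  n <- nrow(labels)
  ord <- if (n) .withSeed(seed * 11L + 3L, sample.int(n)) else integer(0)
  trials <- data.frame(
    trial_id = seq_len(n),
    onset_s = firstOnset + (seq_len(n) - 1L) * config@iti,
    condition = labels$condition[ord],
    laterality = labels$laterality[ord],
    stringsAsFactors = FALSE
  )
  new("StimulusProtocol", trials = trials, iti = config@iti, mode = mode)
}

#' @rdname makeProtocol
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param path CSV file path.
#' @export
writeProtocol <- function(protocol, path) {
  utils::write.csv(protocol@trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname makeProtocol
#' @param iti,mode metadata to attach when reading a plain CSV.
#' @export
readProtocol <- function(path, iti, mode = "duration") {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  new("StimulusProtocol", trials = trials, iti = iti, mode = mode)
}

# Total recording duration implied by a protocol (s).
.recordingDuration <- function(protocol, config) {
  tr <- protocol@trials
  if (nrow(tr) == 0L) return(config@spontDuration)
  max(tr$onset_s) + config@iti
}
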